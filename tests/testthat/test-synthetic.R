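# Kinetic archetypes and the seeded experiment simulator.

test_that("closed-form trajectories evaluate correctly", {
  sub <- kinetic_archetype("SUBSTRATE", amplitude = 100, k = 0.2)
  expect_equal(trajectory(sub, c(0.5, 4, 24)),
               c(90.48374, 44.93290, 0.82297), tolerance = 1e-6)
  prod <- kinetic_archetype("PRODUCT", amplitude = 100, k = 0.2)
  expect_equal(trajectory(prod, c(0.5, 4, 24)),
               100 - c(90.48374, 44.93290, 0.82297), tolerance = 1e-6)
  int <- kinetic_archetype("INTERMEDIATE", amplitude = 1, k1 = 0.3, k2 = 0.5)
  # closed form: 1.5 * (exp(-0.3 t) - exp(-0.5 t))
  expect_equal(trajectory(int, c(0.5, 4, 24)),
               c(0.1228605, 0.2487884, 0.0011107), tolerance = 1e-5)
  # that parameter set is the classic rise-then-fall signature
  tr <- trajectory(int, c(0.5, 4, 24))
  expect_gt(tr[2] / tr[1], 2)
  expect_gt(tr[2] / tr[3], 1.25)
  expect_equal(intermediate_peak_time(int), log(0.5 / 0.3) / 0.2,
               tolerance = 1e-12)
  expect_equal(intermediate_peak_time(int), 2.554128, tolerance = 1e-6)
  expect_error(trajectory(sub, -1), "non-negative")
  expect_error(kinetic_archetype("INTERMEDIATE", 1, k1 = 0.3, k2 = 0.3),
               "k1 != k2")
})

test_that("the sample design covers every channel, time and replicate", {
  d <- sample_design()
  expect_equal(nrow(d), 45)  # 5 channel/concentration cells x 3 times x 3
  expect_setequal(unique(d$channel),
                  c("HFS_WBE", "HFS_VEHICLE", "HFS_PBS", "EXTRACT_CONTROL"))
  expect_setequal(unique(d$wbe_concentration[d$channel == "HFS_WBE"]),
                  c(2, 10))
  expect_true(all(d$wbe_concentration[d$channel %in%
                                        c("HFS_VEHICLE", "HFS_PBS")] == 0))
  expect_setequal(unique(d$time_point), c(0.5, 4, 24))
  counts <- table(d$channel, d$time_point)
  expect_true(all(counts[rownames(counts) != "HFS_WBE", ] == 3))
  expect_true(all(counts["HFS_WBE", ] == 6))  # two concentrations
})

test_that("noiseless simulation reproduces trajectories exactly", {
  cfg <- default_truth_config(2, 2, 2, 2, 1, 1, 1)
  sim <- simulate_experiment(cfg, noise_sigma = 0, lod = 0, seed = 11)
  tab <- sim$table
  truth <- sim$truth
  for (i in seq_len(nrow(truth))) {
    arch <- gutfate:::.archetype_from_truth_row(truth[i, ])
    for (j in seq_len(nrow(tab$design))) {
      expect_equal(
        unname(tab$areas[truth$feature_id[i], tab$design$sample_id[j]]),
        gutfate:::expected_area(arch, tab$design$channel[j],
                                tab$design$wbe_concentration[j],
                                tab$design$time_point[j],
                                inhibition_factor = 1.5),
        tolerance = 1e-12)
    }
  }
})

test_that("extract-control kinetics freeze for biotic archetypes only", {
  sub <- kinetic_archetype("SUBSTRATE", 100, k = 0.2)
  abio <- kinetic_archetype("ABIOTIC_UNSTABLE", 100, k = 0.2)
  t <- c(0.5, 4, 24)
  expect_equal(gutfate:::expected_area(sub, "EXTRACT_CONTROL", 10, t),
               rep(100, 3))
  expect_equal(gutfate:::expected_area(abio, "EXTRACT_CONTROL", 10, t),
               100 * exp(-0.2 * t))
  # extract-derived features are absent from extract-free fecal channels
  expect_equal(gutfate:::expected_area(sub, "HFS_VEHICLE", 0, t), rep(0, 3))
  # matrix features are everywhere except the microbe-free control
  mat <- kinetic_archetype("MATRIX", 50)
  expect_equal(gutfate:::expected_area(mat, "HFS_PBS", 0, t), rep(50, 3))
  expect_equal(gutfate:::expected_area(mat, "EXTRACT_CONTROL", 10, t),
               rep(0, 3))
})

test_that("high-concentration inhibition slows biotic rates only", {
  sub <- kinetic_archetype("SUBSTRATE", 100, k = 0.3)
  lo <- gutfate:::expected_area(sub, "HFS_WBE", 2, 4, inhibition_factor = 2)
  hi <- gutfate:::expected_area(sub, "HFS_WBE", 10, 4, inhibition_factor = 2)
  expect_equal(lo, 100 * exp(-0.3 * 4))
  expect_equal(hi, 100 * exp(-0.15 * 4))
  abio <- kinetic_archetype("ABIOTIC_UNSTABLE", 100, k = 0.3)
  expect_equal(
    gutfate:::expected_area(abio, "HFS_WBE", 10, 4, inhibition_factor = 2),
    100 * exp(-0.3 * 4))
})

test_that("simulation is seed-deterministic and censors below the LOD", {
  cfg <- default_truth_config(3, 3, 3, 3, 2, 2, 2)
  s1 <- simulate_experiment(cfg, noise_sigma = 0.2, lod = 1, seed = 99)
  s2 <- simulate_experiment(cfg, noise_sigma = 0.2, lod = 1, seed = 99)
  expect_identical(s1$table$areas, s2$table$areas)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_experiment(cfg, noise_sigma = 0.2, lod = 1, seed = 100)
  expect_false(identical(s1$table$areas, s3$table$areas))
  # fast-metabolized features are censored in every fecal cell
  fast <- s1$truth$feature_id[s1$truth$archetype == "FAST_METABOLIZED"]
  hfs <- s1$table$design$sample_id[s1$table$design$channel == "HFS_WBE"]
  expect_true(all(is.na(s1$table$areas[fast, hfs])))
  # stable features are never censored (LOD far below amplitude)
  stab <- s1$truth$feature_id[s1$truth$archetype == "STABLE"]
  on_cols <- s1$table$design$sample_id[s1$table$design$channel %in%
                                         c("HFS_WBE", "EXTRACT_CONTROL")]
  expect_false(any(is.na(s1$table$areas[stab, on_cols])))
  expect_error(simulate_experiment(cfg, noise_sigma = -0.1, seed = 1),
               "noise_sigma")
  expect_error(simulate_experiment(cfg, lod = -1, seed = 1), "lod")
  expect_error(simulate_experiment(cfg), "seed")
})
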