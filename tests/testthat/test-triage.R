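# Fate triage: group statistics, fold tests, classification rules, matrix
# and fast-metabolized detection, abiotic crosscheck, and run_triage against
# a brute-force oracle.

make_tiny_table <- function(area_list) {
  # area_list: named list sample_id -> per-feature areas
  design <- sample_design()
  n <- length(area_list[[1]])
  areas <- matrix(NA_real_, n, nrow(design),
                  dimnames = list(sprintf("T%02d", seq_len(n)),
                                  design$sample_id))
  for (sid in names(area_list)) areas[, sid] <- area_list[[sid]]
  feature_table(data.frame(feature_id = rownames(areas),
                           mz = seq(100, 100 + n - 1), rt = rep(5, n)),
                areas, design)
}

test_that("group statistics zero-fill non-detects and gate presence", {
  design <- sample_design()
  areas <- matrix(NA_real_, 3, nrow(design),
                  dimnames = list(c("A", "B", "C"), design$sample_id))
  cols <- design$sample_id[design$channel == "HFS_WBE" &
                             design$wbe_concentration == 2 &
                             design$time_point == 0.5]
  areas["A", cols] <- c(10, 12, 14)
  areas["B", cols] <- c(10, NA, 14)
  areas["C", cols] <- c(NA, NA, 9)
  tab <- feature_table(data.frame(feature_id = c("A", "B", "C"),
                                  mz = 1:3 + 100, rt = rep(1, 3)),
                       areas, design)
  gA <- group_stats(tab, "A", "HFS_WBE", 2, 0.5)
  expect_equal(gA$mean, 12); expect_equal(gA$sd, 2)
  expect_equal(gA$n_detected, 3); expect_true(gA$present)
  gB <- group_stats(tab, "B", "HFS_WBE", 2, 0.5)
  expect_equal(gB$mean, 8)  # ND contributes 0
  expect_equal(gB$n_detected, 2); expect_true(gB$present)
  gC <- group_stats(tab, "C", "HFS_WBE", 2, 0.5)
  expect_equal(gC$n_detected, 1); expect_false(gC$present)
  expect_error(group_stats(tab, "A", "HFS_WBE", 7, 0.5), "not found")
})

test_that("fold_test reproduces the pooled-variance Student t-test", {
  ft <- fold_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ft$ratio, 1); expect_equal(ft$t, 0); expect_equal(ft$p, 1)

  ft <- fold_test(c(10, 12, 14), c(20, 22, 24))
  expect_equal(ft$ratio, 22 / 12, tolerance = 1e-12)
  expect_equal(abs(ft$t), 6.123724, tolerance = 1e-6)
  expect_equal(ft$df, 4)
  expect_equal(ft$p, 0.003602233, tolerance = 1e-6)  # frozen from t.test

  # swap symmetry: ratio inverts, t negates, p unchanged
  rev <- fold_test(c(20, 22, 24), c(10, 12, 14))
  expect_equal(rev$ratio, 1 / ft$ratio, tolerance = 1e-12)
  expect_equal(rev$t, -ft$t, tolerance = 1e-12)
  expect_equal(rev$p, ft$p, tolerance = 1e-12)

  # zero-variance limit rules
  expect_equal(fold_test(c(5, 5, 5), c(5, 5, 5))$p, 1)
  z <- fold_test(c(5, 5, 5), c(9, 9, 9))
  expect_equal(z$p, 0); expect_equal(z$t, Inf)
  # undefined ratio flag when the reference mean is zero
  u <- fold_test(c(0, 0, 0), c(1, 2, 3))
  expect_true(u$ratio_undefined); expect_identical(u$ratio, Inf)
  # insufficient data signalled, not crashed
  expect_true(fold_test(c(1), c(1, 2, 3))$insufficient)
})

test_that("fold_test agrees with stats::t.test on random group pairs", {
  set.seed(101)
  for (i in 1:200) {
    a <- exp(rnorm(sample(2:5, 1), 2, 0.5))
    b <- exp(rnorm(sample(2:5, 1), 2.3, 0.5))
    ft <- fold_test(a, b)
    tt <- stats::t.test(b, a, var.equal = TRUE)
    expect_equal(ft$t, unname(tt$statistic), tolerance = 1e-9)
    expect_equal(ft$p, tt$p.value, tolerance = 1e-9)
    wf <- fold_test(a, b, welch = TRUE)
    wt <- stats::t.test(b, a)
    expect_equal(wf$p, wt$p.value, tolerance = 1e-9)
  }
})

test_that("classification rules and their precedence", {
  mk <- function(ratio, p) structure(list(ratio = ratio, p = p,
                                          insufficient = FALSE),
                                     class = "fold_test")
  # plain increase
  expect_equal(classify_fate(list(t4_vs_t0 = mk(1.2, 0.5),
                                  t24_vs_t0 = mk(3, 0.01),
                                  t4_vs_t24 = mk(0.5, 0.5))), "INCREASING")
  # plain decrease
  expect_equal(classify_fate(list(t4_vs_t0 = mk(0.9, 0.5),
                                  t24_vs_t0 = mk(0.4, 0.01),
                                  t4_vs_t24 = mk(1.1, 0.5))), "DECREASING")
  # intermediate wins over increasing when both rules fire
  expect_equal(classify_fate(list(t4_vs_t0 = mk(2.5, 0.01),
                                  t24_vs_t0 = mk(2.2, 0.01),
                                  t4_vs_t24 = mk(1.5, 0.5))), "INTERMEDIATE")
  # non-significant changes stay unchanged
  expect_equal(classify_fate(list(t4_vs_t0 = mk(3, 0.2),
                                  t24_vs_t0 = mk(3, 0.2),
                                  t4_vs_t24 = mk(2, 0.2))), "UNCHANGED")
  # presence gating
  expect_equal(classify_fate(list(t4_vs_t0 = mk(3, 0.01),
                                  t24_vs_t0 = mk(3, 0.01),
                                  t4_vs_t24 = mk(2, 0.01)),
                             present = FALSE), "INSUFFICIENT_DATA")
})

test_that("matrix and fast-metabolized detection follow the control rules", {
  design <- sample_design()
  n <- 4
  areas <- matrix(NA_real_, n, nrow(design),
                  dimnames = list(c("mat", "ext", "fast", "ghost"),
                                  design$sample_id))
  veh_t0 <- design$sample_id[design$channel == "HFS_VEHICLE" &
                               design$time_point == 0.5]
  areas["mat", veh_t0] <- c(100, 110, 90)
  ec <- design$sample_id[design$channel == "EXTRACT_CONTROL"]
  areas["ext", ec] <- 200
  hfs2_t0 <- design$sample_id[design$channel == "HFS_WBE" &
                                design$wbe_concentration == 2 &
                                design$time_point == 0.5]
  areas["ext", hfs2_t0] <- 150
  areas["fast", ec] <- 300
  tab <- feature_table(data.frame(feature_id = rownames(areas),
                                  mz = 100 + 1:n, rt = rep(1, n)),
                       areas, design)
  expect_true(matrix_filter(tab, "mat"))
  expect_false(matrix_filter(tab, "ext"))
  expect_false(matrix_filter(tab, "fast"))
  # present only in extract control and never in fecal cells -> fast
  expect_true(detect_fast_metabolized(tab, "fast"))
  # present in a fecal cell at t0 -> not fast
  expect_false(detect_fast_metabolized(tab, "ext"))
  # absent everywhere -> not fast (never shown to exist)
  expect_false(detect_fast_metabolized(tab, "ghost"))
})

test_that("abiotic crosscheck flags same-direction control changes only", {
  expect_true(crosscheck_abiotic("DECREASING", "DECREASING"))
  expect_true(crosscheck_abiotic("INCREASING", "INCREASING"))
  expect_false(crosscheck_abiotic("DECREASING", "UNCHANGED"))
  expect_false(crosscheck_abiotic("INCREASING", "DECREASING"))
  expect_false(crosscheck_abiotic("UNCHANGED", "UNCHANGED"))
})

test_that("noiseless archetypes get exactly their expected labels", {
  cfg <- default_truth_config(4, 4, 4, 4, 3, 3, 2)
  sim <- simulate_experiment(cfg, noise_sigma = 0, lod = 1, seed = 5)
  fates <- run_triage(sim$table, pipeline_config())
  truth <- sim$truth
  merged <- merge(fates, truth[, c("feature_id", "archetype")],
                  by = "feature_id")
  expect_true(all(merged$label == expected_label(merged$archetype)))
  # abiotic features flagged, biotic ones not
  expect_true(all(merged$abiotic_flag[merged$archetype ==
                                        "ABIOTIC_UNSTABLE"]))
  expect_false(any(merged$abiotic_flag[merged$archetype %in%
                                         c("SUBSTRATE", "PRODUCT",
                                           "INTERMEDIATE", "STABLE")]))
})

test_that("every (feature, concentration) gets exactly one label", {
  sim <- simulate_experiment(default_truth_config(3, 3, 3, 3, 2, 2, 1),
                             noise_sigma = 0.2, seed = 8)
  fates <- run_triage(sim$table)
  expect_equal(nrow(fates), nrow(sim$truth) * 2)
  expect_false(any(duplicated(fates[, c("feature_id", "concentration")])))
  expect_true(all(fates$label %in% c("MATRIX", "FAST_METABOLIZED",
                                     "INSUFFICIENT_DATA", "INTERMEDIATE",
                                     "INCREASING", "DECREASING",
                                     "UNCHANGED")))
})

test_that("triage is invariant under global area scaling", {
  sim <- simulate_experiment(default_truth_config(3, 3, 3, 3, 2, 1, 1),
                             noise_sigma = 0.15, seed = 21)
  tab <- sim$table
  f1 <- run_triage(tab)
  tab2 <- tab
  tab2$areas <- tab$areas * 1000
  f2 <- run_triage(tab2)
  expect_identical(f1$label, f2$label)
  expect_equal(f1$ratio_t24_t0, f2$ratio_t24_t0, tolerance = 1e-12)
  expect_equal(f1$p_t24_t0, f2$p_t24_t0, tolerance = 1e-9)
})

test_that("run_triage matches a brute-force rule oracle on random tables", {
  set.seed(314)
  for (rep in 1:30) {
    tab <- random_small_table(n_features = 6)
    got <- run_triage(tab)
    want <- oracle_triage(tab)
    expect_identical(got$label, want$label)
    expect_identical(got$abiotic_flag, want$abiotic_flag)
  }
})

test_that("run_triage validates its design", {
  sim <- simulate_experiment(default_truth_config(2, 2, 2, 2, 1, 1, 1),
                             noise_sigma = 0, seed = 3)
  tab <- sim$table
  keep <- !(tab$design$channel == "HFS_WBE" &
              tab$design$wbe_concentration == 2 &
              tab$design$time_point == 4 & tab$design$replicate > 1)
  tab$design <- tab$design[keep, ]
  tab$areas <- tab$areas[, tab$design$sample_id]
  expect_error(run_triage(tab), "fewer than 2 replicates")
})
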