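# Seeded simulator of the incubation experiment: known kinetic ground truth
# per feature, so every downstream stage is testable without raw data.

ARCHETYPES <- c("SUBSTRATE", "INTERMEDIATE", "PRODUCT", "STABLE",
                "ABIOTIC_UNSTABLE", "MATRIX", "FAST_METABOLIZED")

#' Define a kinetic archetype
#'
#' A kinetic archetype is the noiseless time course of one feature class
#' during incubation: first-order decay of an extract constituent
#' (`SUBSTRATE`), first-order formation of a microbial metabolite
#' (`PRODUCT`), rise-then-fall of a transient intermediate (`INTERMEDIATE`,
#' the middle species of a two-step series A -> B -> C), a constant level
#' (`STABLE` or the extract-independent `MATRIX` background), chemical decay
#' that also happens without microbes (`ABIOTIC_UNSTABLE`), and decay so fast
#' that the compound is never seen in fecal incubations
#' (`FAST_METABOLIZED`, implemented as a substrate with a very large rate).
#'
#' @param kind One of `r paste(ARCHETYPES, collapse = ", ")`.
#' @param amplitude Initial (or asymptotic, for `PRODUCT`) area, > 0.
#' @param k Rate constant per hour (decay/formation kinds).
#' @param k1,k2 Formation and onward-degradation rates per hour
#'   (`INTERMEDIATE` only); must differ.
#' @return A `kinetic_archetype` object.
#' @export
kinetic_archetype <- function(kind, amplitude, k = NULL, k1 = NULL,
                              k2 = NULL) {
  kind <- match.arg(kind, ARCHETYPES)
  stopifnot(is.numeric(amplitude), amplitude > 0)
  needs_k <- kind %in% c("SUBSTRATE", "PRODUCT", "ABIOTIC_UNSTABLE",
                         "FAST_METABOLIZED")
  if (needs_k && (is.null(k) || k <= 0)) {
    stop(kind, " requires a positive rate constant k", call. = FALSE)
  }
  if (kind == "INTERMEDIATE") {
    if (is.null(k1) || is.null(k2) || k1 <= 0 || k2 <= 0) {
      stop("INTERMEDIATE requires positive rates k1 and k2", call. = FALSE)
    }
    if (k1 == k2) stop("INTERMEDIATE requires k1 != k2", call. = FALSE)
  }
  structure(list(kind = kind, amplitude = amplitude, k = k, k1 = k1,
                 k2 = k2), class = "kinetic_archetype")
}

#' Noiseless trajectory of a kinetic archetype
#'
#' Evaluates the closed-form expected peak area at time `t` (hours) in a
#' microbially active channel. Rate constants may be slowed by a
#' concentration-dependent inhibition via `rate_scale` (< 1 slows).
#'
#' @param archetype A [kinetic_archetype()].
#' @param t Time in hours, >= 0 (vectorized).
#' @param rate_scale Multiplier applied to the biotic rate constants;
#'   abiotic decay is never scaled.
#' @return Expected area(s), same length as `t`.
#' @export
#' @examples
#' sub <- kinetic_archetype("SUBSTRATE", amplitude = 100, k = 0.2)
#' trajectory(sub, c(0.5, 4, 24))
trajectory <- function(archetype, t, rate_scale = 1) {
  stopifnot(inherits(archetype, "kinetic_archetype"))
  if (any(t < 0)) stop("time must be non-negative", call. = FALSE)
  A <- archetype$amplitude
  switch(archetype$kind,
    SUBSTRATE = ,
    FAST_METABOLIZED = A * exp(-archetype$k * rate_scale * t),
    ABIOTIC_UNSTABLE = A * exp(-archetype$k * t),
    PRODUCT = A * (1 - exp(-archetype$k * rate_scale * t)),
    INTERMEDIATE = {
      k1 <- archetype$k1 * rate_scale
      k2 <- archetype$k2 * rate_scale
      A * k1 / (k2 - k1) * (exp(-k1 * t) - exp(-k2 * t))
    },
    STABLE = ,
    MATRIX = rep(A, length(t)))
}

#' Peak time of an intermediate trajectory
#'
#' The rise-then-fall series solution peaks at `log(k2/k1) / (k2 - k1)`.
#'
#' @param archetype An `INTERMEDIATE` [kinetic_archetype()].
#' @return Peak time in hours.
#' @export
intermediate_peak_time <- function(archetype) {
  stopifnot(inherits(archetype, "kinetic_archetype"),
            archetype$kind == "INTERMEDIATE")
  log(archetype$k2 / archetype$k1) / (archetype$k2 - archetype$k1)
}

# Channel-aware expected area. Extract-derived features are absent from the
# extract-free fecal channels; matrix features are present in every fecal
# channel and absent from the microbe-free extract control; biotic kinetics
# freeze in the extract control (substrates sit at their initial level,
# products and intermediates never form) while abiotic decay proceeds
# everywhere the compound is present.
expected_area <- function(archetype, channel, wbe_concentration, t,
                          inhibition_factor = 1) {
  stopifnot(inherits(archetype, "kinetic_archetype"))
  kind <- archetype$kind
  A <- archetype$amplitude
  if (kind == "MATRIX") {
    return(if (channel == "EXTRACT_CONTROL") rep(0, length(t))
           else rep(A, length(t)))
  }
  if (channel %in% c("HFS_VEHICLE", "HFS_PBS")) {
    return(rep(0, length(t)))          # extract-derived, no extract added
  }
  if (channel == "EXTRACT_CONTROL") {
    return(switch(kind,
      SUBSTRATE = , FAST_METABOLIZED = , STABLE = rep(A, length(t)),
      PRODUCT = , INTERMEDIATE = rep(0, length(t)),
      ABIOTIC_UNSTABLE = trajectory(archetype, t)))
  }
  # HFS_WBE: biotic rates slowed at the high concentration
  scale <- if (wbe_concentration >= 10) 1 / inhibition_factor else 1
  trajectory(archetype, t, rate_scale = scale)
}

#' Default ground-truth configuration for the simulator
#'
#' Builds the per-feature ground truth of a simulated incubation: archetype
#' counts, rate constants and amplitudes. The default rates are chosen so
#' that every archetype's closed-form group ratios clear the classification
#' thresholds at both extract concentrations (including the 1.5-fold rate
#' inhibition applied at 10 mg/ml).
#'
#' @param n_substrate,n_product,n_intermediate,n_stable Features per biotic
#'   archetype.
#' @param n_abiotic Features decaying abiotically (also in the microbe-free
#'   extract control).
#' @param n_matrix Fecal-background features present without extract.
#' @param n_fast Features metabolized too fast to ever be seen in fecal
#'   incubations.
#' @param amplitude Baseline peak area (area units).
#' @param k_substrate,k_product,k_abiotic,k_fast First-order rate constants
#'   per hour.
#' @param k1_intermediate,k2_intermediate Formation/degradation rates of the
#'   intermediate archetype per hour.
#' @param inhibition_factor Dimensionless factor (>= 1) dividing biotic rates
#'   at 10 mg/ml, emulating slower turnover at the high concentration.
#' @return A list of class `truth_config` with elements `features` (data
#'   frame: `feature_id`, `archetype`, `amplitude`, `k`, `k1`, `k2`, `mz`,
#'   `rt`, `compound`) and `inhibition_factor`.
#' @export
default_truth_config <- function(n_substrate = 50, n_product = 50,
                                 n_intermediate = 50, n_stable = 50,
                                 n_abiotic = 20, n_matrix = 10, n_fast = 5,
                                 amplitude = 1000,
                                 k_substrate = 0.2, k_product = 0.2,
                                 k1_intermediate = 0.35,
                                 k2_intermediate = 0.10,
                                 k_abiotic = 0.15, k_fast = 30,
                                 inhibition_factor = 1.5) {
  stopifnot(inhibition_factor >= 1, amplitude > 0)
  counts <- c(SUBSTRATE = n_substrate, PRODUCT = n_product,
              INTERMEDIATE = n_intermediate, STABLE = n_stable,
              ABIOTIC_UNSTABLE = n_abiotic, MATRIX = n_matrix,
              FAST_METABOLIZED = n_fast)
  stopifnot(all(counts >= 0))
  archetype <- rep(names(counts), counts)
  n <- length(archetype)
  k <- c(SUBSTRATE = k_substrate, PRODUCT = k_product,
         INTERMEDIATE = NA_real_, STABLE = NA_real_,
         ABIOTIC_UNSTABLE = k_abiotic, MATRIX = NA_real_,
         FAST_METABOLIZED = k_fast)[archetype]
  features <- data.frame(
    feature_id = sprintf("F%04d", seq_len(n)),
    archetype = archetype,
    amplitude = amplitude,
    k = unname(k),
    k1 = ifelse(archetype == "INTERMEDIATE", k1_intermediate, NA_real_),
    k2 = ifelse(archetype == "INTERMEDIATE", k2_intermediate, NA_real_),
    mz = NA_real_, rt = NA_real_, compound = NA_character_,
    stringsAsFactors = FALSE)
  structure(list(features = features, inhibition_factor = inhibition_factor),
            class = "truth_config")
}

.archetype_from_truth_row <- function(row) {
  kinetic_archetype(row$archetype, amplitude = row$amplitude,
                    k = if (is.na(row$k)) NULL else row$k,
                    k1 = if (is.na(row$k1)) NULL else row$k1,
                    k2 = if (is.na(row$k2)) NULL else row$k2)
}

#' Simulate a full incubation experiment
#'
#' Generates a feature table under the incubation design with multiplicative
#' lognormal noise and limit-of-detection censoring, together with the
#' ground truth used to generate it. Identical seeds give bit-identical
#' tables.
#'
#' @param truth_config A [default_truth_config()] (possibly modified).
#' @param noise_sigma Standard deviation of the lognormal noise on the log
#'   scale; `0` gives exact trajectories.
#' @param lod Limit of detection (area units); observed areas below it are
#'   recorded as not detected (`NA`). The default is far below the default
#'   amplitude so stable features are never censored.
#' @param seed Integer seed; mandatory.
#' @param design Sample design; defaults to [sample_design()].
#' @return A list with elements `table` (a [feature_table()]) and `truth`
#'   (the resolved per-feature ground truth, with the simulation parameters
#'   as attributes).
#' @export
#' @examples
#' sim <- simulate_experiment(default_truth_config(5, 5, 5, 5, 2, 2, 1),
#'                            noise_sigma = 0.1, seed = 1)
#' sim$table
simulate_experiment <- function(truth_config = default_truth_config(),
                                noise_sigma = 0.2, lod = 1, seed,
                                design = sample_design()) {
  if (missing(seed) || is.null(seed)) {
    stop("a seed is required for reproducible simulation", call. = FALSE)
  }
  if (!is.numeric(noise_sigma) || noise_sigma < 0) {
    stop("noise_sigma must be >= 0", call. = FALSE)
  }
  if (!is.numeric(lod) || lod < 0) stop("lod must be >= 0", call. = FALSE)
  stopifnot(inherits(truth_config, "truth_config"))
  validate_design(design)
  truth <- truth_config$features
  inhibition <- truth_config$inhibition_factor
  n <- nrow(truth)

  set.seed(as.integer(seed))
  # fill unanchored m/z and RT with plausible values
  fill_mz <- is.na(truth$mz)
  truth$mz[fill_mz] <- round(stats::runif(sum(fill_mz), 100, 900), 5)
  fill_rt <- is.na(truth$rt)
  truth$rt[fill_rt] <- round(stats::runif(sum(fill_rt), 1, 36), 2)

  expected <- matrix(0, nrow = n, ncol = nrow(design),
                     dimnames = list(truth$feature_id, design$sample_id))
  for (i in seq_len(n)) {
    arch <- .archetype_from_truth_row(truth[i, ])
    for (j in seq_len(nrow(design))) {
      expected[i, j] <- expected_area(arch, design$channel[j],
                                      design$wbe_concentration[j],
                                      design$time_point[j],
                                      inhibition_factor = inhibition)
    }
  }
  noise <- if (noise_sigma > 0) {
    matrix(exp(stats::rnorm(length(expected), 0, noise_sigma)),
           nrow = n)
  } else {
    matrix(1, nrow = n, ncol = ncol(expected))
  }
  observed <- expected * noise
  observed[observed < lod] <- NA_real_

  features <- truth[, c("feature_id", "mz", "rt")]
  tab <- feature_table(features, observed, design)
  attr(truth, "seed") <- as.integer(seed)
  attr(truth, "noise_sigma") <- noise_sigma
  attr(truth, "lod") <- lod
  attr(truth, "inhibition_factor") <- inhibition
  list(table = tab, truth = truth)
}

#' Expected triage label per ground-truth archetype
#'
#' The label each archetype should receive from fate triage when its
#' kinetics clear the classification thresholds: substrates decrease,
#' products increase, intermediates rise and fall, stable features are
#' unchanged, abiotically unstable features decrease (and should be flagged
#' by the extract-control crosscheck), matrix features are excluded as
#' matrix, and fast-metabolized features are never seen in fecal channels.
#'
#' @param archetype Character vector of archetype kinds.
#' @return Character vector of expected fate labels.
#' @export
expected_label <- function(archetype) {
  map <- c(SUBSTRATE = "DECREASING", PRODUCT = "INCREASING",
           INTERMEDIATE = "INTERMEDIATE", STABLE = "UNCHANGED",
           ABIOTIC_UNSTABLE = "DECREASING", MATRIX = "MATRIX",
           FAST_METABOLIZED = "FAST_METABOLIZED")
  unname(map[archetype])
}
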