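# Fate triage: classify every feature's time-course behavior per extract
# concentration from group ratios and pooled-variance t-tests, exclude the
# fecal matrix background, and crosscheck against the microbe-free extract
# control to rule out abiotic changes.

FATE_LABELS <- c("MATRIX", "FAST_METABOLIZED", "INSUFFICIENT_DATA",
                 "INTERMEDIATE", "INCREASING", "DECREASING", "UNCHANGED")

#' Per-cell group statistics
#'
#' Summary statistics of one (feature, channel, concentration, time) design
#' cell. Not-detected replicates contribute an area of 0 to the mean and
#' standard deviation (areas below the limit of detection are effectively
#' zero), while `n_detected` counts only detected replicates. A feature is
#' "present" in a cell when at least `min_detected` of its replicates are
#' detected.
#'
#' @param table A [feature_table()].
#' @param feature_id Feature id (row of the table).
#' @param channel,wbe_concentration,time_point The design cell.
#' @param min_detected Detected replicates needed for presence (default 2 of
#'   3).
#' @return A list with `mean`, `sd`, `n_total`, `n_detected`, `present` and
#'   the zero-filled replicate `values`.
#' @export
group_stats <- function(table, feature_id, channel, wbe_concentration,
                        time_point, min_detected = 2) {
  raw <- cell_areas(table, feature_id, channel, wbe_concentration,
                    time_point)
  values <- ifelse(is.na(raw), 0, raw)
  n_detected <- sum(!is.na(raw))
  list(mean = mean(values), sd = stats::sd(values), n_total = length(raw),
       n_detected = n_detected, present = n_detected >= min_detected,
       values = unname(values))
}

#' Group-ratio fold test
#'
#' The triage procedure's two-group comparison: the ratio of group means with
#' an unpaired, two-tailed Student's t-test assuming equal variances
#' (pooled-variance statistic, `df = n_a + n_b - 2`). Zero-variance groups
#' (possible in noiseless simulations) take the limit values: p = 1 when the
#' means are equal, p = 0 when they differ. When `mean(a)` is zero the ratio
#' is infinite (+Inf if `mean(b) > 0`, NaN if both are zero) and the
#' `ratio_undefined` flag is set.
#'
#' @param a,b Numeric replicate areas (not-detected already zero-filled);
#'   each needs at least 2 values.
#' @param welch Use Welch's unequal-variance test instead of the pooled
#'   test.
#' @return A list of class `fold_test`: `ratio` (= `mean(b)/mean(a)`),
#'   `t`, `df`, `p`, `n_a`, `n_b`, `ratio_undefined`, `insufficient`.
#' @export
#' @examples
#' fold_test(c(10, 12, 14), c(20, 22, 24))
fold_test <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2) {
    return(structure(list(ratio = NA_real_, t = NA_real_, df = NA_real_,
                          p = NA_real_, n_a = length(a), n_b = length(b),
                          ratio_undefined = NA, insufficient = TRUE),
                     class = "fold_test"))
  }
  ma <- mean(a); mb <- mean(b)
  ratio <- if (ma == 0) {
    if (mb > 0) Inf else NaN
  } else {
    mb / ma
  }
  va <- stats::var(a); vb <- stats::var(b)
  na <- length(a); nb <- length(b)
  if (va == 0 && vb == 0) {
    if (ma == mb) {
      t <- 0; p <- 1
    } else {
      t <- sign(mb - ma) * Inf; p <- 0
    }
    df <- na + nb - 2
  } else if (welch) {
    se2 <- va / na + vb / nb
    t <- (mb - ma) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * stats::pt(-abs(t), df)
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    t <- (mb - ma) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
    p <- 2 * stats::pt(-abs(t), df)
  }
  structure(list(ratio = ratio, t = t, df = df, p = p, n_a = na, n_b = nb,
                 ratio_undefined = (ma == 0), insufficient = FALSE),
            class = "fold_test")
}

#' @export
print.fold_test <- function(x, ...) {
  if (isTRUE(x$insufficient)) {
    cat("<fold_test> insufficient data (n =", x$n_a, "vs", x$n_b, ")\n")
  } else {
    cat(sprintf("<fold_test> ratio %.4g, t %.4g (df %g), p %.4g\n",
                x$ratio, x$t, x$df, x$p))
  }
  invisible(x)
}

#' Classify a feature's fate from its ratio tests
#'
#' Applies the classification rules: a feature is an intermediate when
#' t4/t0 > `up` with p < `alpha` and t4/t24 > `inter` (rise then fall);
#' otherwise significantly increasing when t24/t0 > `up` with p < `alpha`;
#' otherwise significantly decreasing when t24/t0 < `down` with p < `alpha`;
#' otherwise unchanged. The intermediate rule is evaluated first because a
#' rise-fall feature can also satisfy the increasing or decreasing rule.
#' `INSUFFICIENT_DATA` is returned when the feature is not present in any
#' time-point group (`present = FALSE`) or a required test is missing.
#'
#' @param tests Named list with `fold_test` elements `t4_vs_t0`, `t24_vs_t0`
#'   and `t4_vs_t24`.
#' @param present Logical: is the feature present (detected in enough
#'   replicates) in at least one time-point group of this channel?
#' @param alpha Significance level (default 0.05, unadjusted).
#' @param up Fold threshold for increase (default 2).
#' @param down Fold threshold for decrease (default 0.5).
#' @param inter t4/t24 fold threshold of the intermediate rule (default
#'   1.25).
#' @return One of `"INTERMEDIATE"`, `"INCREASING"`, `"DECREASING"`,
#'   `"UNCHANGED"`, `"INSUFFICIENT_DATA"`.
#' @export
classify_fate <- function(tests, present = TRUE, alpha = 0.05, up = 2,
                          down = 0.5, inter = 1.25) {
  need <- c("t4_vs_t0", "t24_vs_t0", "t4_vs_t24")
  if (!all(need %in% names(tests))) {
    stop("tests must contain ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (!isTRUE(present) ||
      any(vapply(tests[need], function(x) isTRUE(x$insufficient),
                 logical(1)))) {
    return("INSUFFICIENT_DATA")
  }
  t40 <- tests$t4_vs_t0; t240 <- tests$t24_vs_t0; t424 <- tests$t4_vs_t24
  if (isTRUE(t40$ratio > up) && isTRUE(t40$p < alpha) &&
      isTRUE(t424$ratio > inter)) {
    return("INTERMEDIATE")
  }
  if (isTRUE(t240$ratio > up) && isTRUE(t240$p < alpha)) {
    return("INCREASING")
  }
  if (isTRUE(t240$ratio < down) && isTRUE(t240$p < alpha)) {
    return("DECREASING")
  }
  "UNCHANGED"
}

#' Is a feature part of the fecal matrix background?
#'
#' A feature is a matrix peak when it is present (detected in at least
#' `min_detected` replicates) in any extract-free fecal channel (vehicle or
#' PBS control) at any time point: it is then contained in the fecal matrix
#' and cannot be an extract constituent or metabolite.
#'
#' @inheritParams group_stats
#' @return `TRUE` if the feature is a matrix peak.
#' @export
matrix_filter <- function(table, feature_id, min_detected = 2) {
  design <- table$design
  free <- design[design$channel %in% c("HFS_VEHICLE", "HFS_PBS"), ]
  if (nrow(free) == 0L) {
    stop("no extract-free fecal control channel (HFS_VEHICLE/HFS_PBS) in design",
         call. = FALSE)
  }
  cells <- unique(free[, c("channel", "wbe_concentration", "time_point")])
  for (i in seq_len(nrow(cells))) {
    gs <- group_stats(table, feature_id, cells$channel[i],
                      cells$wbe_concentration[i], cells$time_point[i],
                      min_detected = min_detected)
    if (gs$present) return(TRUE)
  }
  FALSE
}

#' Was a feature metabolized too fast to be seen?
#'
#' Detects extract constituents that are already undetectable at the first
#' sampling of every fecal incubation: the feature must be present in the
#' microbe-free extract control at the first time point (so it demonstrably
#' exists in the extract) and absent from every extract-treated fecal cell
#' at every time point.
#'
#' @inheritParams group_stats
#' @return `TRUE` if the feature qualifies as fast-metabolized.
#' @export
detect_fast_metabolized <- function(table, feature_id, min_detected = 2) {
  design <- table$design
  ec <- design[design$channel == "EXTRACT_CONTROL", ]
  if (nrow(ec) == 0L) {
    stop("no EXTRACT_CONTROL channel in design", call. = FALSE)
  }
  t0 <- min(ec$time_point)
  ec_cells <- unique(ec[ec$time_point == t0,
                        c("channel", "wbe_concentration", "time_point")])
  in_extract <- any(vapply(seq_len(nrow(ec_cells)), function(i) {
    group_stats(table, feature_id, ec_cells$channel[i],
                ec_cells$wbe_concentration[i], ec_cells$time_point[i],
                min_detected = min_detected)$present
  }, logical(1)))
  if (!in_extract) return(FALSE)
  hfs <- unique(design[design$channel == "HFS_WBE",
                       c("channel", "wbe_concentration", "time_point")])
  for (i in seq_len(nrow(hfs))) {
    gs <- group_stats(table, feature_id, hfs$channel[i],
                      hfs$wbe_concentration[i], hfs$time_point[i],
                      min_detected = min_detected)
    if (gs$present) return(FALSE)
  }
  TRUE
}

#' Crosscheck a fecal-channel fate against the extract control
#'
#' Flags a change as abiotic when the microbe-free extract control shows the
#' same-direction significant change over time (increasing in both, or
#' decreasing in both): such a change is not caused by incubation with the
#' fecal suspension. Flagged features should be excluded from microbial
#' substrate/metabolite reports.
#'
#' @param fate_hfs Fate label in the fecal channel.
#' @param fate_extract_control Fate label in the extract control.
#' @return Logical abiotic flag.
#' @export
crosscheck_abiotic <- function(fate_hfs, fate_extract_control) {
  (fate_hfs == "INCREASING" && fate_extract_control == "INCREASING") ||
    (fate_hfs == "DECREASING" && fate_extract_control == "DECREASING")
}

# Fate of one feature within one channel/concentration: the three ratio
# tests plus the label.
.channel_fate <- function(table, feature_id, channel, conc, times, config) {
  gs <- lapply(times, function(tp) {
    group_stats(table, feature_id, channel, conc, tp,
                min_detected = config$min_detected)
  })
  names(gs) <- c("t0", "t4", "t24")
  tests <- list(
    t4_vs_t0 = fold_test(gs$t0$values, gs$t4$values, welch = config$welch),
    t24_vs_t0 = fold_test(gs$t0$values, gs$t24$values, welch = config$welch),
    t4_vs_t24 = fold_test(gs$t24$values, gs$t4$values, welch = config$welch))
  present_any <- any(vapply(gs, `[[`, logical(1), "present"))
  label <- classify_fate(tests, present = present_any, alpha = config$alpha,
                         up = config$up, down = config$down,
                         inter = config$inter)
  list(label = label, tests = tests, present = present_any)
}

#' Run fate triage over a feature table
#'
#' Classifies every feature at every extract concentration. Matrix peaks
#' (present in an extract-free fecal channel) and fast-metabolized features
#' (present in the extract control but never in fecal incubations) take
#' precedence over the ratio-based labels; each concentration is compared
#' against its own first time point; the abiotic flag is attached from the
#' extract-control crosscheck and is independent of the label.
#'
#' @param table A [feature_table()]. The design must contain the `HFS_WBE`
#'   channel, at least one extract-free fecal channel and (for the fast and
#'   abiotic rules) the `EXTRACT_CONTROL` channel, each with three time
#'   points.
#' @param config A [pipeline_config()]; thresholds and test options are
#'   taken from it.
#' @return A data frame with one row per (feature, concentration):
#'   `feature_id`, `concentration`, `label`, the three ratios with their t
#'   statistics and p-values, `extract_control_label`, `abiotic_flag`.
#' @export
run_triage <- function(table, config = pipeline_config()) {
  stopifnot(inherits(table, "feature_table"))
  design <- table$design
  times <- sort(unique(design$time_point))
  if (length(times) != 3L) {
    stop("triage expects exactly three time points, got ",
         length(times), call. = FALSE)
  }
  concs <- sort(unique(design$wbe_concentration[design$channel == "HFS_WBE"]))
  if (length(concs) == 0L) stop("no HFS_WBE samples in design", call. = FALSE)
  # validate completeness: every needed cell must have >= 2 replicates
  needed <- design[design$channel %in% c("HFS_WBE", "EXTRACT_CONTROL"), ]
  cell_n <- stats::aggregate(replicate ~ channel + wbe_concentration +
                               time_point, data = needed, FUN = length)
  thin <- cell_n[cell_n$replicate < 2, ]
  if (nrow(thin)) {
    stop("design cells with fewer than 2 replicates: ",
         paste(sprintf("%s/c%g/t%g", thin$channel, thin$wbe_concentration,
                       thin$time_point), collapse = "; "), call. = FALSE)
  }

  ec_conc <- unique(design$wbe_concentration[design$channel ==
                                               "EXTRACT_CONTROL"])
  has_ec <- length(ec_conc) > 0L
  ids <- table$features$feature_id
  rows <- vector("list", length(ids) * length(concs))
  r <- 0L
  for (id in ids) {
    is_matrix <- matrix_filter(table, id, min_detected = config$min_detected)
    is_fast <- if (has_ec) {
      detect_fast_metabolized(table, id, min_detected = config$min_detected)
    } else {
      FALSE
    }
    ec_fate <- if (has_ec) {
      .channel_fate(table, id, "EXTRACT_CONTROL", ec_conc[1], times, config)
    } else {
      NULL
    }
    for (conc in concs) {
      cf <- .channel_fate(table, id, "HFS_WBE", conc, times, config)
      label <- if (is_matrix) {
        "MATRIX"
      } else if (is_fast) {
        "FAST_METABOLIZED"
      } else {
        cf$label
      }
      ec_label <- if (has_ec) ec_fate$label else NA_character_
      abiotic <- if (has_ec) {
        crosscheck_abiotic(cf$label, ec_label)
      } else {
        NA
      }
      tt <- cf$tests
      r <- r + 1L
      rows[[r]] <- data.frame(
        feature_id = id, concentration = conc, label = label,
        ratio_t4_t0 = tt$t4_vs_t0$ratio, t_t4_t0 = tt$t4_vs_t0$t,
        p_t4_t0 = tt$t4_vs_t0$p,
        ratio_t24_t0 = tt$t24_vs_t0$ratio, t_t24_t0 = tt$t24_vs_t0$t,
        p_t24_t0 = tt$t24_vs_t0$p,
        ratio_t4_t24 = tt$t4_vs_t24$ratio, t_t4_t24 = tt$t4_vs_t24$t,
        p_t4_t24 = tt$t4_vs_t24$p,
        matrix_flag = is_matrix, fast_flag = is_fast,
        extract_control_label = ec_label, abiotic_flag = abiotic,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
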