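# Independent brute-force re-application of the fate rules, used as an
# oracle against run_triage(). Deliberately written from the rule text with
# stats::t.test as the significance engine, sharing no code with the
# implementation.

oracle_triage <- function(table, alpha = 0.05, up = 2, down = 0.5,
                          inter = 1.25) {
  design <- table$design
  areas <- table$areas
  times <- sort(unique(design$time_point))
  concs <- sort(unique(design$wbe_concentration[design$channel == "HFS_WBE"]))

  vals <- function(id, channel, conc, tp) {
    sel <- design$channel == channel & design$wbe_concentration == conc &
      design$time_point == tp
    areas[id, design$sample_id[sel]]
  }
  present <- function(id, channel, conc, tp) {
    sum(!is.na(vals(id, channel, conc, tp))) >= 2
  }
  pval <- function(x, y) {
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      if (mean(x) == mean(y)) 1 else 0
    } else {
      stats::t.test(y, x, var.equal = TRUE)$p.value
    }
  }
  rat <- function(x, y) if (mean(x) == 0) Inf * sign(mean(y)) else
    mean(y) / mean(x)

  out <- NULL
  for (id in table$features$feature_id) {
    is_matrix <- any(vapply(times, function(tp) {
      present(id, "HFS_VEHICLE", 0, tp) || present(id, "HFS_PBS", 0, tp)
    }, logical(1)))
    ec_conc <- unique(design$wbe_concentration[design$channel ==
                                                 "EXTRACT_CONTROL"])[1]
    in_ec_t0 <- present(id, "EXTRACT_CONTROL", ec_conc, min(times))
    in_hfs_any <- any(vapply(concs, function(cc) {
      any(vapply(times, function(tp) present(id, "HFS_WBE", cc, tp),
                 logical(1)))
    }, logical(1)))
    is_fast <- in_ec_t0 && !in_hfs_any

    rate_label <- function(channel, cc) {
      z <- lapply(times, function(tp) {
        v <- vals(id, channel, cc, tp)
        ifelse(is.na(v), 0, v)
      })
      any_present <- any(vapply(times, function(tp)
        present(id, channel, cc, tp), logical(1)))
      if (!any_present) return("INSUFFICIENT_DATA")
      r40 <- rat(z[[1]], z[[2]]); p40 <- pval(z[[1]], z[[2]])
      r240 <- rat(z[[1]], z[[3]]); p240 <- pval(z[[1]], z[[3]])
      r424 <- rat(z[[3]], z[[2]])
      if (!is.nan(r40) && r40 > up && p40 < alpha &&
          !is.nan(r424) && r424 > inter) return("INTERMEDIATE")
      if (!is.nan(r240) && r240 > up && p240 < alpha) return("INCREASING")
      if (!is.nan(r240) && r240 < down && p240 < alpha) return("DECREASING")
      "UNCHANGED"
    }

    for (cc in concs) {
      hfs_label <- rate_label("HFS_WBE", cc)
      label <- if (is_matrix) "MATRIX" else if (is_fast) "FAST_METABOLIZED"
        else hfs_label
      ec_label <- rate_label("EXTRACT_CONTROL", ec_conc)
      abiotic <- (hfs_label == "INCREASING" && ec_label == "INCREASING") ||
        (hfs_label == "DECREASING" && ec_label == "DECREASING")
      out <- rbind(out, data.frame(feature_id = id, concentration = cc,
                                   label = label, abiotic_flag = abiotic,
                                   stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

# A random small feature table with diverse, sometimes degenerate patterns.
random_small_table <- function(n_features = 8) {
  design <- sample_design()
  ids <- sprintf("R%03d", seq_len(n_features))
  areas <- matrix(NA_real_, n_features, nrow(design),
                  dimnames = list(ids, design$sample_id))
  for (i in seq_len(n_features)) {
    kind <- sample(c("trend_up", "trend_down", "flat", "bump", "sparse",
                     "matrixy"), 1)
    base <- stats::runif(1, 50, 500)
    lvl <- switch(kind,
      trend_up = c(1, stats::runif(1, 1, 6), stats::runif(1, 1, 10)),
      trend_down = c(1, stats::runif(1, 0.2, 1), stats::runif(1, 0.02, 1)),
      flat = c(1, 1, 1),
      bump = c(1, stats::runif(1, 1.2, 6), stats::runif(1, 0.1, 2)),
      sparse = c(0, 0, stats::runif(1, 0, 2)),
      matrixy = c(1, 1, 1))
    for (j in seq_len(nrow(design))) {
      ch <- design$channel[j]
      tp_idx <- match(design$time_point[j], sort(unique(design$time_point)))
      mu <- base * lvl[tp_idx]
      present_here <- switch(kind,
        matrixy = ch != "EXTRACT_CONTROL",
        ch %in% c("HFS_WBE", "EXTRACT_CONTROL"))
      if (present_here && mu > 0) {
        a <- mu * exp(stats::rnorm(1, 0, 0.25))
        # random dropouts create presence edge cases
        areas[i, j] <- if (stats::runif(1) < 0.12) NA_real_ else a
      }
    }
  }
  feature_table(data.frame(feature_id = ids,
                           mz = stats::runif(n_features, 100, 900),
                           rt = stats::runif(n_features, 1, 36)),
                areas, design)
}
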