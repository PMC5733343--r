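# Annotation of features against a compound library by theoretical
# monoisotopic mass (ppm tolerance), with optional retention-time gating.

#' Match one feature against a compound library
#'
#' Converts the observed negative-mode m/z to a neutral mass, then returns
#' every library compound whose theoretical formula-derived mass lies within
#' `ppm_tol`. Matching is against theoretical masses, not the library's
#' printed observed masses. When `rt_tol` is given (minutes) and the feature
#' has a retention time, candidates must also elute within that window —
#' retention times are method-specific, so gating is off by default. Hits
#' are ranked by |delta ppm|, then |delta RT|, then peak id, which makes tie
#' ordering total and deterministic.
#'
#' @param mz Observed m/z of the feature (Th, negative mode).
#' @param rt Retention time of the feature (minutes), or `NA`.
#' @param library A [load_compound_library()] result.
#' @param ppm_tol Mass tolerance in ppm (default 5).
#' @param rt_tol Retention-time tolerance in minutes, or `NULL`/`NA` to
#'   disable gating.
#' @return A data frame of hits (possibly empty): `peak_id`, `name`,
#'   `theoretical_mass`, `delta_ppm`, `delta_rt`.
#' @export
#' @examples
#' lib <- load_compound_library()
#' match_feature(285.09798, rt = 6.7, library = lib)  # salicin
match_feature <- function(mz, rt = NA_real_, library, ppm_tol = 5,
                          rt_tol = NULL) {
  stopifnot(inherits(library, "compound_library"))
  if (!is.numeric(ppm_tol) || ppm_tol <= 0) {
    stop("ppm_tol must be positive", call. = FALSE)
  }
  neutral <- neutral_from_negmode_mz(mz)
  delta <- ppm_delta(neutral, library$theoretical_mass)
  delta_rt <- if (is.na(rt)) rep(NA_real_, nrow(library)) else rt - library$rt_min
  keep <- abs(delta) <= ppm_tol
  gate_rt <- !is.null(rt_tol) && !is.na(rt_tol)
  if (gate_rt) {
    if (rt_tol <= 0) stop("rt_tol must be positive", call. = FALSE)
    keep <- keep & !is.na(delta_rt) & abs(delta_rt) <= rt_tol
  }
  hits <- data.frame(peak_id = library$peak_id[keep],
                     name = library$name[keep],
                     theoretical_mass = library$theoretical_mass[keep],
                     delta_ppm = delta[keep],
                     delta_rt = delta_rt[keep],
                     stringsAsFactors = FALSE)
  ord <- order(abs(hits$delta_ppm),
               ifelse(is.na(hits$delta_rt), Inf, abs(hits$delta_rt)),
               hits$peak_id)
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Annotate every feature of a table
#'
#' Runs [match_feature()] over all features and returns one row per hit,
#' keyed by feature id. Features without a hit are absent from the report
#' (an empty match is a valid result).
#'
#' @param table A [feature_table()].
#' @param library A [load_compound_library()] result.
#' @param ppm_tol,rt_tol As in [match_feature()].
#' @return A data frame: `feature_id`, `rank`, `peak_id`, `name`,
#'   `theoretical_mass`, `delta_ppm`, `delta_rt`.
#' @export
annotate_features <- function(table, library = load_compound_library(),
                              ppm_tol = 5, rt_tol = NULL) {
  stopifnot(inherits(table, "feature_table"))
  feats <- table$features
  out <- lapply(seq_len(nrow(feats)), function(i) {
    hits <- match_feature(feats$mz[i], feats$rt[i], library,
                          ppm_tol = ppm_tol, rt_tol = rt_tol)
    if (nrow(hits) == 0L) return(NULL)
    cbind(data.frame(feature_id = feats$feature_id[i],
                     rank = seq_len(nrow(hits)),
                     stringsAsFactors = FALSE),
          hits)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(feature_id = character(), rank = integer(),
                      peak_id = integer(), name = character(),
                      theoretical_mass = numeric(), delta_ppm = numeric(),
                      delta_rt = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
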