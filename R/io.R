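# Readers, writers, configuration, and the pipeline driver.
#
# Interchange format is delimited text (tab or comma, autodetected on read,
# tab on write). Not-detected cells are written as the literal token "ND" so
# they survive a round trip as distinct from zero.

ND_TOKEN <- "ND"

.detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Write / read a feature table
#'
#' The feature table is stored as two delimited files: the table itself
#' (feature_id, mz, rt, one column per sample; `ND` marks not-detected) and
#' the sample design. A write followed by a read restores an identical
#' object.
#'
#' @param table A [feature_table()].
#' @param path Path of the feature-table file.
#' @param design_path Path of the design file; defaults to `path` with a
#'   `_design` suffix.
#' @return `write_feature_table()` returns the paths invisibly;
#'   `read_feature_table()` returns a [feature_table()].
#' @export
write_feature_table <- function(table, path,
                                design_path = default_design_path(path)) {
  stopifnot(inherits(table, "feature_table"))
  areas <- table$areas
  out <- cbind(table$features,
               as.data.frame(ifelse(is.na(areas), ND_TOKEN,
                                    format(areas, digits = 15, trim = TRUE,
                                           scientific = FALSE))))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(table$design, design_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, design_path))
}

#' @rdname write_feature_table
#' @export
default_design_path <- function(path) {
  sub("(\\.[^.]+)?$", "_design\\1", path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path, design_path = default_design_path(path)) {
  for (p in c(path, design_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  sep <- .detect_sep(path)
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "")
  design <- utils::read.table(design_path, sep = .detect_sep(design_path),
                              header = TRUE, stringsAsFactors = FALSE,
                              check.names = FALSE, quote = "")
  meta_cols <- c("feature_id", "mz", "rt")
  missing <- setdiff(meta_cols, names(raw))
  if (length(missing)) {
    stop("feature table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sample_cols <- setdiff(names(raw), meta_cols)
  areas <- as.matrix(raw[, sample_cols, drop = FALSE])
  areas[areas == ND_TOKEN] <- NA
  suppressWarnings(storage.mode(areas) <- "double")
  bad <- is.na(areas) & !(as.matrix(raw[, sample_cols, drop = FALSE]) ==
                            ND_TOKEN)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop("non-numeric area at row ", w[1], ", column '",
         sample_cols[w[2]], "'", call. = FALSE)
  }
  feature_table(raw[, meta_cols], areas, design)
}

#' Pipeline configuration
#'
#' Collects and validates every tunable of the pipeline: the fold and
#' significance thresholds of fate classification, the annotation
#' tolerances, the detection rules, and the simulation parameters.
#'
#' @param up Fold threshold for a significant increase (t24/t0 > `up`);
#'   must exceed 1.
#' @param down Fold threshold for a significant decrease (t24/t0 < `down`);
#'   in (0, 1).
#' @param inter t4/t24 fold threshold of the intermediate rule; > 1.
#' @param alpha Raw significance level of the t-tests, in (0, 1). No
#'   multiple-testing correction is applied; see the vignette.
#' @param ppm_tol Annotation mass tolerance in ppm.
#' @param rt_tol Annotation retention-time tolerance in minutes, or `NULL`
#'   (disabled).
#' @param lod Limit of detection (area units).
#' @param min_detected Replicates that must be detected for presence.
#' @param welch Use Welch's t-test instead of the pooled-variance Student
#'   test.
#' @param noise_sigma Lognormal noise sd of the simulator.
#' @param seed Integer seed; mandatory when the pipeline simulates.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(up = 2, down = 0.5, inter = 1.25, alpha = 0.05,
                            ppm_tol = 5, rt_tol = NULL, lod = 1,
                            min_detected = 2, welch = FALSE,
                            noise_sigma = 0.2, seed = NULL) {
  if (!is.numeric(up) || up <= 1) stop("up must be > 1", call. = FALSE)
  if (!is.numeric(down) || down <= 0 || down >= 1) {
    stop("down must be in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(inter) || inter <= 1) {
    stop("inter must be > 1", call. = FALSE)
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(ppm_tol) || ppm_tol <= 0) {
    stop("ppm_tol must be positive", call. = FALSE)
  }
  if (!is.null(rt_tol) && (!is.numeric(rt_tol) || rt_tol <= 0)) {
    stop("rt_tol must be positive or NULL", call. = FALSE)
  }
  if (!is.numeric(lod) || lod < 0) stop("lod must be >= 0", call. = FALSE)
  if (!is.numeric(min_detected) || min_detected < 1) {
    stop("min_detected must be >= 1", call. = FALSE)
  }
  if (!is.numeric(noise_sigma) || noise_sigma < 0) {
    stop("noise_sigma must be >= 0", call. = FALSE)
  }
  structure(list(up = up, down = down, inter = inter, alpha = alpha,
                 ppm_tol = ppm_tol, rt_tol = rt_tol, lod = lod,
                 min_detected = min_detected, welch = isTRUE(welch),
                 noise_sigma = noise_sigma, seed = seed),
            class = "pipeline_config")
}

.config_lines <- function(config) {
  vals <- vapply(config, function(v) {
    if (is.null(v)) "NULL" else paste(format(v), collapse = ",")
  }, character(1))
  sprintf("config %s = %s", names(config), vals)
}

#' Run the full pipeline
#'
#' Simulates (or reads) a feature table, triages every feature's fate at
#' each extract concentration, annotates features against the compound
#' library, and overlays the annotated fates on the bundled degradation
#' pathways. Deterministic given the configuration and seed.
#'
#' @param config A [pipeline_config()]. `config$seed` is mandatory unless
#'   `table` is supplied.
#' @param table An existing [feature_table()]; if `NULL`, a table is
#'   simulated from `truth_config`.
#' @param truth_config Ground truth for simulation; defaults to
#'   [default_truth_config()] anchored to the compound library via
#'   [demo_truth_config()] being a convenient alternative.
#' @param library Compound library for annotation.
#' @param pathways Character vector of pathway fixtures to overlay.
#' @param overlay_concentration Extract concentration whose fates are
#'   overlaid (default 2 mg/ml).
#' @return A list of class `pipeline_result`: `table`, `truth` (or `NULL`),
#'   `fates`, `annotations`, `overlays` (one [overlay_fates()] result per
#'   pathway), `log` (character vector; every threshold and every excluded
#'   feature with its reason), and the echoed `config`.
#' @export
run_pipeline <- function(config = pipeline_config(seed = 1), table = NULL,
                         truth_config = default_truth_config(),
                         library = load_compound_library(),
                         pathways = c("naringenin", "catechin", "salicyl"),
                         overlay_concentration = 2) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- c("stage config", .config_lines(config))
  truth <- NULL
  if (is.null(table)) {
    if (is.null(config$seed)) {
      stop("config$seed is mandatory for simulation", call. = FALSE)
    }
    sim <- tryCatch(
      simulate_experiment(truth_config, noise_sigma = config$noise_sigma,
                          lod = config$lod, seed = config$seed),
      error = function(e) stop("stage simulate: ", conditionMessage(e),
                               call. = FALSE))
    table <- sim$table
    truth <- sim$truth
    log <- c(log, sprintf("stage simulate: %d features, %d samples, seed %d",
                          nrow(table$features), nrow(table$design),
                          config$seed))
  }
  fates <- tryCatch(run_triage(table, config),
                    error = function(e) stop("stage triage: ",
                                             conditionMessage(e),
                                             call. = FALSE))
  excl <- fates[fates$label %in% c("MATRIX", "FAST_METABOLIZED",
                                   "INSUFFICIENT_DATA") |
                  fates$abiotic_flag %in% TRUE, ]
  reason <- ifelse(excl$abiotic_flag %in% TRUE &
                     !excl$label %in% c("MATRIX", "FAST_METABOLIZED",
                                        "INSUFFICIENT_DATA"),
                   "abiotic", tolower(excl$label))
  log <- c(log,
           sprintf("stage triage: %d fate records", nrow(fates)),
           sprintf("excluded %s (c%g): %s", excl$feature_id,
                   excl$concentration, reason))
  annotations <- tryCatch(
    annotate_features(table, library, ppm_tol = config$ppm_tol,
                      rt_tol = config$rt_tol),
    error = function(e) stop("stage annotate: ", conditionMessage(e),
                             call. = FALSE))
  log <- c(log, sprintf("stage annotate: %d hits for %d features",
                        nrow(annotations),
                        length(unique(annotations$feature_id))))
  cf <- compound_fates(fates, annotations,
                       concentration = overlay_concentration)
  overlays <- lapply(pathways, function(p) {
    tryCatch({
      pw <- load_pathway(p)
      overlay_fates(pw, cf[names(cf) %in% pw$nodes$name])
    }, error = function(e) stop("stage pathway (", p, "): ",
                                conditionMessage(e), call. = FALSE))
  })
  names(overlays) <- pathways
  log <- c(log, sprintf("stage pathway (%s): coverage %.2f", pathways,
                        vapply(overlays, `[[`, numeric(1), "coverage")))
  structure(list(table = table, truth = truth, fates = fates,
                 annotations = annotations, overlays = overlays, log = log,
                 config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  fates: ", nrow(x$fates), " records; labels: ",
      paste(names(table(x$fates$label)), collapse = ", "), "\n", sep = "")
  cat("  annotations: ", nrow(x$annotations), " hits\n", sep = "")
  for (p in names(x$overlays)) {
    cat(sprintf("  overlay %s: coverage %.2f\n", p,
                x$overlays[[p]]$coverage))
  }
  invisible(x)
}

#' Ground truth anchored to the bundled compound library
#'
#' A small, fully anchored truth configuration for demonstrations and
#' end-to-end tests: extract glycosides behave as substrates, known gut
#' metabolites as products, naringenin and the valerolactones as
#' intermediates, catechol as stable, the grandidentatins as abiotically
#' unstable, the trimeric procyanidin and HCH-acetylsalicortin as
#' fast-metabolized, and a few unanchored matrix features. Feature m/z and
#' RT are set to each compound's theoretical negative-mode values so the
#' annotation stage recovers the names.
#'
#' @param library Compound library used for anchoring.
#' @return A `truth_config` (see [default_truth_config()]).
#' @export
demo_truth_config <- function(library = load_compound_library()) {
  pick <- function(ids) library[match(ids, library$peak_id), ]
  anchor <- function(ids, archetype, k = NA_real_, k1 = NA_real_,
                     k2 = NA_real_) {
    rec <- pick(ids)
    data.frame(feature_id = sprintf("P%02d", ids), archetype = archetype,
               amplitude = 1000, k = k, k1 = k1, k2 = k2,
               mz = rec$mz, rt = rec$rt_min, compound = rec$name,
               stringsAsFactors = FALSE)
  }
  feats <- rbind(
    anchor(c(10, 19, 7, 37, 41, 47, 44, 30, 40, 18), "SUBSTRATE", k = 0.2),
    anchor(c(56, 28, 13), "INTERMEDIATE", k1 = 0.35, k2 = 0.10),
    anchor(c(6, 12, 14, 15, 38, 17, 34, 49, 16, 42, 54, 20, 35),
           "PRODUCT", k = 0.2),
    anchor(8, "STABLE"),
    anchor(c(51, 53), "ABIOTIC_UNSTABLE", k = 0.15),
    anchor(c(26, 57, 31), "FAST_METABOLIZED", k = 30),
    data.frame(feature_id = sprintf("M%02d", 1:5), archetype = "MATRIX",
               amplitude = 1000, k = NA_real_, k1 = NA_real_,
               k2 = NA_real_, mz = NA_real_, rt = NA_real_,
               compound = NA_character_, stringsAsFactors = FALSE))
  structure(list(features = feats, inhibition_factor = 1.5),
            class = "truth_config")
}

#' Write a triage report
#'
#' One row per (feature, concentration) with a stable column order; the
#' configuration is echoed as comment lines at the top for provenance.
#'
#' @param fates A [run_triage()] report.
#' @param path Output path.
#' @param config Optional [pipeline_config()] echoed into the header.
#' @return The path, invisibly.
#' @export
write_fate_report <- function(fates, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config)) {
    writeLines(paste0("# ", .config_lines(config)), con)
  }
  utils::write.table(fates, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_fate_report
#' @export
read_fate_report <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, comment.char = "#")
}
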