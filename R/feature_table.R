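# The pipeline's central object: features (m/z, RT) x samples (peak areas),
# tied to a sample design.

CHANNELS <- c("HFS_WBE", "HFS_VEHICLE", "HFS_PBS", "EXTRACT_CONTROL")

#' Construct the incubation sample design
#'
#' Builds the full factorial sample design of the incubation experiment:
#' fecal suspension with extract at two concentrations, a vehicle control and
#' a PBS control (both extract-free), and an extract-in-buffer control
#' without microbes, each sampled in triplicate at three time points.
#'
#' @param time_points Sampling times in hours. The labels t0/t4/t24 map to
#'   the defaults 0.5, 4 and 24 h (the first sample is drawn 30 min after
#'   extract addition).
#' @param replicates Number of replicates per design cell.
#' @param concentrations Extract concentrations (mg/ml) of the treated
#'   channels.
#' @param extract_control_concentration Concentration used in the
#'   microbe-free extract control.
#' @return A data frame with columns `sample_id`, `channel`,
#'   `wbe_concentration`, `time_point`, `replicate`.
#' @export
#' @examples
#' d <- sample_design()
#' nrow(d)  # 45
sample_design <- function(time_points = c(0.5, 4, 24), replicates = 3,
                          concentrations = c(2, 10),
                          extract_control_concentration = 10) {
  stopifnot(length(time_points) >= 2, all(time_points >= 0),
            replicates >= 2, all(concentrations > 0))
  cells <- rbind(
    data.frame(channel = "HFS_WBE", wbe_concentration = concentrations),
    data.frame(channel = "HFS_VEHICLE", wbe_concentration = 0),
    data.frame(channel = "HFS_PBS", wbe_concentration = 0),
    data.frame(channel = "EXTRACT_CONTROL",
               wbe_concentration = extract_control_concentration))
  design <- merge(merge(cells, data.frame(time_point = time_points)),
                  data.frame(replicate = seq_len(replicates)))
  design <- design[order(match(design$channel, CHANNELS),
                         design$wbe_concentration, design$time_point,
                         design$replicate), ]
  design$sample_id <- sprintf("%s_c%g_t%g_r%d", design$channel,
                              design$wbe_concentration, design$time_point,
                              design$replicate)
  rownames(design) <- NULL
  design[, c("sample_id", "channel", "wbe_concentration", "time_point",
             "replicate")]
}

validate_design <- function(design) {
  req <- c("sample_id", "channel", "wbe_concentration", "time_point",
           "replicate")
  missing <- setdiff(req, names(design))
  if (length(missing)) {
    stop("design is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(design$sample_id)) {
    stop("duplicate sample_id in design", call. = FALSE)
  }
  bad <- setdiff(unique(design$channel), CHANNELS)
  if (length(bad)) {
    stop("unknown channel(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  free <- design$channel %in% c("HFS_VEHICLE", "HFS_PBS")
  if (any(design$wbe_concentration[free] != 0)) {
    stop("extract-free control channels must have concentration 0",
         call. = FALSE)
  }
  if (any(design$wbe_concentration[design$channel == "HFS_WBE"] <= 0)) {
    stop("HFS_WBE samples must have a positive extract concentration",
         call. = FALSE)
  }
  invisible(design)
}

#' Construct a feature table
#'
#' Bundles the feature metadata (id, m/z, retention time), the area matrix
#' and the sample design into one validated object. Areas below the limit of
#' detection are stored as `NA` ("not detected"), which is distinct from an
#' observed zero.
#'
#' @param features Data frame with columns `feature_id` (unique), `mz`, `rt`.
#' @param areas Numeric matrix, features x samples; `NA` = not detected.
#' @param design Sample design as from [sample_design()]; must cover every
#'   column of `areas`.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(features, areas, design) {
  req <- c("feature_id", "mz", "rt")
  missing <- setdiff(req, names(features))
  if (length(missing)) {
    stop("features is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(features$feature_id)) {
    stop("duplicate feature_id: ",
         paste(unique(features$feature_id[duplicated(features$feature_id)]),
               collapse = ", "), call. = FALSE)
  }
  validate_design(design)
  areas <- as.matrix(areas)
  if (nrow(areas) != nrow(features)) {
    stop("areas has ", nrow(areas), " rows but features has ",
         nrow(features), call. = FALSE)
  }
  if (is.null(colnames(areas))) {
    stop("areas must have sample ids as column names", call. = FALSE)
  }
  unknown <- setdiff(colnames(areas), design$sample_id)
  if (length(unknown)) {
    stop("sample column(s) not in design: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  absent <- setdiff(design$sample_id, colnames(areas))
  if (length(absent)) {
    stop("design sample(s) missing from areas: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  if (any(areas < 0, na.rm = TRUE)) {
    bad <- which(areas < 0, arr.ind = TRUE)[1, ]
    stop("negative area at feature row ", bad[1], ", sample column ", bad[2],
         call. = FALSE)
  }
  rownames(areas) <- features$feature_id
  areas <- areas[, design$sample_id, drop = FALSE]
  structure(list(features = as.data.frame(features), areas = areas,
                 design = as.data.frame(design)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x$features), " features x ",
      nrow(x$design), " samples\n", sep = "")
  cat("  channels: ", paste(unique(x$design$channel), collapse = ", "), "\n",
      sep = "")
  cat("  time points (h): ",
      paste(sort(unique(x$design$time_point)), collapse = ", "), "\n",
      sep = "")
  nd <- sum(is.na(x$areas))
  cat("  not-detected cells: ", nd, " of ", length(x$areas), "\n", sep = "")
  invisible(x)
}

# Replicate areas of one design cell; NA kept (not detected).
cell_areas <- function(table, feature_id, channel, wbe_concentration,
                       time_point) {
  sel <- table$design$channel == channel &
    table$design$wbe_concentration == wbe_concentration &
    table$design$time_point == time_point
  if (!any(sel)) {
    stop("design cell not found: ", channel, " / ", wbe_concentration,
         " mg/ml / ", time_point, " h", call. = FALSE)
  }
  table$areas[feature_id, table$design$sample_id[sel]]
}
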