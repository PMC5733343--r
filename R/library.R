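# The bundled willow-bark compound library and its loader.

#' Load a compound library
#'
#' Reads a delimited compound library (by default the bundled willow-bark
#' library of 58 compounds) and computes the theoretical neutral monoisotopic
#' mass of every record from its molecular formula. Printed masses and ppm
#' deviations from the source table are retained verbatim alongside; two
#' records whose printed formula and printed mass disagree carry a curation
#' note in the `note` column and their printed values are not "fixed".
#'
#' @param path Path to a tab-delimited library file. Defaults to the bundled
#'   library.
#' @return A data frame of class `compound_library` with one row per
#'   compound: `peak_id`, `name`, `rt_min`, `printed_mass`, `formula`,
#'   `printed_delta_ppm`, `identification_level` (`REFERENCE_COMPOUND` or
#'   `TENTATIVE`), `salix_described`, `known_gut_metabolite`, `note`, and the
#'   computed `theoretical_mass` (Da) and expected negative-mode `mz`.
#' @export
#' @examples
#' lib <- load_compound_library()
#' nrow(lib)                  # 58
#' lib[lib$name == "salicin", c("formula", "theoretical_mass")]
load_compound_library <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "compound_library.tsv",
                        package = "gutfate", mustWork = TRUE)
  }
  if (!file.exists(path)) stop("library file not found: ", path, call. = FALSE)
  tab <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, fill = TRUE,
                      quote = ""),
    error = function(e) stop("cannot parse library file: ", conditionMessage(e),
                             call. = FALSE))
  required <- c("peak_id", "name", "rt_min", "printed_mass", "formula",
                "printed_delta_ppm", "identification_level",
                "salix_described", "known_gut_metabolite")
  missing <- setdiff(required, names(tab))
  if (length(missing) || nrow(tab) == 0L) {
    stop("library file invalid: ",
         if (nrow(tab) == 0L) "no records" else
           paste("missing columns:", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  if (!"note" %in% names(tab)) tab$note <- NA_character_
  tab$note[!is.na(tab$note) & !nzchar(tab$note)] <- NA_character_
  dup <- tab$peak_id[duplicated(tab$peak_id)]
  if (length(dup)) {
    stop("duplicate peak_id in library: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad_lvl <- !tab$identification_level %in% c("REFERENCE_COMPOUND", "TENTATIVE")
  if (any(bad_lvl)) {
    stop("invalid identification_level in row(s) ",
         paste(which(bad_lvl), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(tab$rt_min) | tab$rt_min <= 0)) {
    stop("retention times must be positive", call. = FALSE)
  }
  tab$theoretical_mass <- vapply(seq_len(nrow(tab)), function(i) {
    tryCatch(monoisotopic_mass(tab$formula[i]),
             error = function(e) stop("row ", i, " (peak ", tab$peak_id[i],
                                      "): ", conditionMessage(e),
                                      call. = FALSE))
  }, numeric(1))
  tab$mz <- mz_from_neutral(tab$theoretical_mass)
  class(tab) <- c("compound_library", "data.frame")
  tab
}
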