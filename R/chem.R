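# Molecular-formula arithmetic for negative-mode LC-MS annotation.

# Exact masses of the lightest stable isotopes, loaded once from the bundled
# table at namespace load (see .onLoad in zzz.R).
the <- new.env(parent = emptyenv())

#: mass of the proton in Da; used for [M-H]- <-> neutral conversion so that
#: the electron mass is accounted for (not the hydrogen-atom mass).
PROTON_MASS <- 1.007276467

#' Exact isotope masses used for monoisotopic-mass calculation
#'
#' Returns the bundled table of lightest-stable-isotope exact masses for the
#' supported elements (C, H, N, O, P, S), in Da. Carbon is 12 by definition.
#'
#' @return A data frame with columns `element` and `mass_Da`.
#' @export
#' @examples
#' isotope_masses()
isotope_masses <- function() {
  if (is.null(the$isotopes)) {
    path <- system.file("extdata", "isotope_masses.tsv", package = "gutfate",
                        mustWork = TRUE)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    the$isotopes <- stats::setNames(tab$mass_Da, tab$element)
  }
  data.frame(element = names(the$isotopes), mass_Da = unname(the$isotopes),
             stringsAsFactors = FALSE)
}

.isotope_lookup <- function() {
  isotope_masses()   # ensures cache
  the$isotopes
}

#' Parse a molecular formula string
#'
#' Parses formulas of the form `"C13H18O7"` into per-element atom counts.
#' An omitted count means one atom, element order is irrelevant, and repeated
#' element symbols are summed. Only the elements C, H, N, O, P and S are
#' accepted; anything else fails loudly rather than silently.
#'
#' @param text Formula string, e.g. `"C13H18O7"` or `"H2O"`.
#' @return An object of class `formula_counts`: a named integer vector of
#'   atom counts.
#' @export
#' @examples
#' parse_formula("C13H18O7")   # salicin
#' parse_formula("C10H13O3NS") # a cysteine adduct
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(text)) {
    stop("formula must be a single non-empty string", call. = FALSE)
  }
  txt <- gsub("[[:space:]]", "", text)
  parts <- regmatches(txt, gregexpr("[A-Z][a-z]?[0-9]*", txt))[[1L]]
  if (sum(nchar(parts)) != nchar(txt)) {
    bad <- substr(gsub(paste(parts, collapse = "|"), "", txt, fixed = FALSE), 1, 8)
    stop("malformed formula '", text, "': unparseable token near '",
         bad, "'", call. = FALSE)
  }
  supported <- names(.isotope_lookup())
  counts <- integer(0)
  for (p in parts) {
    elem <- sub("[0-9]*$", "", p)
    num <- sub("^[A-Za-z]+", "", p)
    if (!elem %in% supported) {
      stop("unsupported element '", elem, "' in formula '", text, "'",
           call. = FALSE)
    }
    n <- if (nzchar(num)) suppressWarnings(as.integer(num)) else 1L
    if (is.na(n) || n == 0L) {
      stop("invalid count '", num, "' for element '", elem, "' in formula '",
           text, "'", call. = FALSE)
    }
    counts[elem] <- (if (elem %in% names(counts)) counts[[elem]] else 0L) + n
  }
  structure(counts, class = "formula_counts")
}

#' @export
print.formula_counts <- function(x, ...) {
  cat("<formula>", paste0(names(x), unclass(x), collapse = " "), "\n")
  invisible(x)
}

#' Neutral monoisotopic mass of a formula
#'
#' Sums count times exact lightest-isotope mass over the elements of the
#' formula, using the bundled isotope table.
#'
#' @param f A `formula_counts` object from [parse_formula()], or a formula
#'   string which is parsed first.
#' @return Monoisotopic mass in Da (positive scalar).
#' @export
#' @examples
#' monoisotopic_mass("C15H12O5") # naringenin, 272.06847 Da
monoisotopic_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  if (!inherits(f, "formula_counts")) {
    stop("'f' must be a formula string or formula_counts", call. = FALSE)
  }
  masses <- .isotope_lookup()
  sum(unclass(f) * masses[names(f)])
}

#' Convert an observed negative-mode m/z to a neutral mass
#'
#' For the deprotonated ion \eqn{[M-H]^-} observed in negative electrospray,
#' the neutral monoisotopic mass is the observed m/z plus the proton mass.
#' Using the proton mass (1.007276 Da) rather than the hydrogen-atom mass
#' keeps the electron mass on the correct side of the ledger.
#'
#' @param mz Observed m/z (Th); must exceed the proton mass.
#' @return Neutral mass in Da.
#' @seealso [mz_from_neutral()] for the inverse.
#' @export
#' @examples
#' neutral_from_negmode_mz(285.09798) # ~ salicin neutral mass
neutral_from_negmode_mz <- function(mz) {
  if (!is.numeric(mz) || any(is.na(mz)) || any(mz <= PROTON_MASS)) {
    stop("m/z must exceed the proton mass (", PROTON_MASS, " Da)",
         call. = FALSE)
  }
  mz + PROTON_MASS
}

#' Expected negative-mode m/z of a neutral mass
#'
#' Inverse of [neutral_from_negmode_mz()]: subtracts the proton mass to give
#' the \eqn{[M-H]^-} m/z. The round trip is exact.
#'
#' @param neutral Neutral monoisotopic mass in Da; must be positive.
#' @return m/z in Th.
#' @export
mz_from_neutral <- function(neutral) {
  if (!is.numeric(neutral) || any(is.na(neutral)) || any(neutral <= 0)) {
    stop("neutral mass must be positive", call. = FALSE)
  }
  neutral - PROTON_MASS
}

#' Signed mass deviation in parts per million
#'
#' @param observed Observed mass (Da).
#' @param theoretical Theoretical mass (Da); must be positive.
#' @return Signed deviation in ppm: `1e6 * (observed - theoretical) /
#'   theoretical`.
#' @export
#' @examples
#' ppm_delta(286.1055, 286.10525)
ppm_delta <- function(observed, theoretical) {
  if (!is.numeric(theoretical) || any(is.na(theoretical)) ||
      any(theoretical <= 0)) {
    stop("theoretical mass must be positive", call. = FALSE)
  }
  1e6 * (observed - theoretical) / theoretical
}
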