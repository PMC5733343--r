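# Minimal OTU-table utilities: rare-OTU filtering, total-sum normalization,
# abundant-taxon selection. Upstream 16S processing (OTU picking, taxonomy
# assignment, ordination) is out of scope.

.check_otu_table <- function(table) {
  m <- as.matrix(table)
  if (!is.numeric(m)) stop("OTU table must be numeric", call. = FALSE)
  if (any(m < 0, na.rm = TRUE)) {
    stop("OTU counts must be non-negative", call. = FALSE)
  }
  if (!is.null(colnames(m)) && anyDuplicated(colnames(m))) {
    stop("duplicate sample ids in OTU table", call. = FALSE)
  }
  m
}

#' Remove rare OTUs
#'
#' Drops OTUs represented by fewer than `min_total` sequences in total
#' across all samples. The default keeps OTUs with at least 6 reads, i.e.
#' removes those represented by 5 or fewer sequences.
#'
#' @param table Numeric matrix or data frame, OTUs (rows) x samples
#'   (columns).
#' @param min_total Minimum total count (across all samples) an OTU must
#'   reach to be kept.
#' @return The filtered table (same type of object, rows dropped).
#' @export
#' @examples
#' m <- rbind(A = c(2, 3), B = c(3, 3))
#' filter_rare_otus(m)   # keeps B only (total 6)
filter_rare_otus <- function(table, min_total = 6) {
  m <- .check_otu_table(table)
  if (nrow(m) == 0L) return(table)
  keep <- rowSums(m) >= min_total
  table[keep, , drop = FALSE]
}

#' Total-sum normalization
#'
#' Divides each sample's counts by the sample total, so every column sums
#' to 1. Applying it twice is a no-op.
#'
#' @param table Numeric matrix or data frame, OTUs x samples; every sample
#'   must have a positive total.
#' @return Matrix of relative abundances with the same dimnames.
#' @export
total_sum_normalize <- function(table) {
  m <- .check_otu_table(table)
  if (ncol(m) == 0L || nrow(m) == 0L) return(m)
  totals <- colSums(m)
  zero <- totals == 0
  if (any(zero)) {
    nm <- colnames(m)[zero]
    if (is.null(nm)) nm <- which(zero)
    stop("zero-total sample(s): ", paste(nm, collapse = ", "),
         call. = FALSE)
  }
  sweep(m, 2, totals, "/")
}

#' Abundant taxa
#'
#' OTUs whose relative abundance strictly exceeds `threshold` in at least
#' one sample (default > 1 %).
#'
#' @param rel_table Relative-abundance matrix as produced by
#'   [total_sum_normalize()].
#' @param threshold Strict relative-abundance cut (default 0.01).
#' @return Character vector of OTU ids (rownames), possibly empty.
#' @export
abundant_taxa <- function(rel_table, threshold = 0.01) {
  m <- as.matrix(rel_table)
  if (nrow(m) == 0L) return(character(0))
  if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
  keep <- apply(m, 1, function(x) any(x > threshold, na.rm = TRUE))
  rownames(m)[keep]
}
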