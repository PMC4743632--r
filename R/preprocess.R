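#' Filter genes with mostly-low read counts
#'
#' Removes genes whose normalized read count is below `min_count` in more
#' than `max_fraction` of samples (strictly more; a gene sitting exactly at
#' the boundary fraction is retained). Intended for raw normalized counts,
#' before log transformation.
#'
#' @param m Numeric genes x samples matrix of nonnegative counts.
#' @param min_count Count threshold; values strictly below it count as low.
#'   Default 20.
#' @param max_fraction Maximum tolerated fraction of low samples. Default 0.5.
#' @return The matrix restricted to retained genes (order preserved). May
#'   have zero rows.
#' @export
filter_low_counts <- function(m, min_count = 20, max_fraction = 0.5) {
  check_expression_matrix(m)
  keep <- rowMeans(m < min_count) <= max_fraction
  m[keep, , drop = FALSE]
}

#' Shifted log2 transform
#'
#' Replaces each value `v` by `log2(v + pseudocount)`; used on normalized
#' read counts (e.g. TPM) ahead of distribution comparison.
#'
#' @param m Numeric matrix with nonnegative values.
#' @param pseudocount Offset added before taking logs. Default 1.
#' @return Transformed matrix of the same shape.
#' @export
log2_transform <- function(m, pseudocount = 1) {
  check_expression_matrix(m)
  if (any(m < 0)) stop("log2_transform requires nonnegative values")
  log2(m + pseudocount)
}

#' Quantile normalization across samples
#'
#' Standard quantile normalization: within each column values are ranked and
#' the r-th ranked value in every column is replaced by the mean of the r-th
#' order statistics across columns, so that (absent ties) all columns share
#' the same sorted values. Ties receive the mean of the normalized values
#' over their tied rank span. Delegates to [limma::normalizeQuantiles()],
#' which implements exactly this convention.
#'
#' @param m Numeric genes x samples matrix with at least 2 columns.
#' @return Normalized matrix, same shape and dimnames.
#' @export
quantile_normalize <- function(m) {
  check_expression_matrix(m)
  if (ncol(m) < 2L) stop("quantile normalization needs at least 2 samples")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}
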