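#' Read a gene expression matrix from delimited text
#'
#' Expects genes in rows: the first column holds gene identifiers, the header
#' row holds sample identifiers and the body is numeric. Missing or
#' non-numeric cells are rejected with their coordinates, as are duplicate
#' gene or sample identifiers.
#'
#' @param path Path to a TSV/CSV file.
#' @param delimiter Field delimiter, default tab.
#' @return A numeric matrix (genes x samples) with gene ids as `rownames` and
#'   sample ids as `colnames`.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\tS1\tS2", "g1\t1.5\t2", "g2\t0\t3"), f)
#' read_expression(f)
#' @export
read_expression <- function(path, delimiter = "\t") {
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          quote = "\"", comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) {
    stop("expression file must have a gene-id column plus at least one sample column")
  }
  gene_ids <- df[[1L]]
  sample_ids <- colnames(df)[-1L]
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g)) {
    stop("duplicate gene id(s): ", paste(dup_g, collapse = ", "))
  }
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s)) {
    stop("duplicate sample id(s): ", paste(dup_s, collapse = ", "))
  }
  body <- as.matrix(df[, -1L, drop = FALSE])
  values <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop(sprintf("non-numeric or missing value at gene '%s', sample '%s' (row %d, column %d): '%s'",
                 gene_ids[i], sample_ids[j], i, j, body[i, j]))
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  values
}

#' Read two-class sample labels
#'
#' Reads a two-column delimited file (sample id, class name; no header).
#' Exactly two distinct class names must be present. The first level of the
#' returned factor is "class 1" (the fold-change denominator); by default
#' levels follow first appearance in the file, which `classes` overrides.
#'
#' @param path Path to the label file.
#' @param delimiter Field delimiter, default tab.
#' @param classes Optional length-2 character vector fixing the class order.
#' @return A factor of class names with two levels, named by sample id.
#' @export
read_labels <- function(path, delimiter = "\t", classes = NULL) {
  df <- utils::read.table(path, sep = delimiter, header = FALSE,
                          colClasses = "character", comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("label file must have two columns: sample id, class")
  as_class_labels(stats::setNames(df[[2L]], df[[1L]]), classes = classes)
}

#' Coerce a named vector/factor to validated two-class labels
#'
#' @param labels Factor or character vector of class names, named by sample id.
#' @param classes Optional length-2 character vector fixing which class is
#'   "class 1". Defaults to order of first appearance.
#' @return A two-level factor named by sample id.
#' @export
as_class_labels <- function(labels, classes = NULL) {
  if (is.null(names(labels)) || any(!nzchar(names(labels)))) {
    stop("labels must be named by sample id")
  }
  dup <- unique(names(labels)[duplicated(names(labels))])
  if (length(dup)) stop("duplicate sample id(s) in labels: ", paste(dup, collapse = ", "))
  cls <- as.character(labels)
  found <- unique(cls)
  if (length(found) != 2L) {
    stop("expected exactly 2 distinct classes, found ", length(found),
         ": ", paste(found, collapse = ", "))
  }
  if (is.null(classes)) classes <- found
  if (length(classes) != 2L || !setequal(classes, found)) {
    stop("'classes' must name the two classes present (",
         paste(found, collapse = ", "), ")")
  }
  stats::setNames(factor(cls, levels = classes), names(labels))
}

# Match labels to the columns of an expression matrix; error on any
# unlabelled sample. Returns the labels reordered to the column order.
pair_labels <- function(m, labels, classes = NULL) {
  labels <- as_class_labels(labels, classes = classes)
  missing <- setdiff(colnames(m), names(labels))
  if (length(missing)) {
    stop("sample(s) without class label: ", paste(missing, collapse = ", "))
  }
  out <- labels[colnames(m)]
  for (cl in levels(out)) {
    if (sum(out == cl) < 1L) stop("class '", cl, "' has no samples in the matrix")
  }
  out
}

#' Write a per-gene result table to TSV
#'
#' Columns: `gene`, `score`, `null_median`, `q_value`, `fold_change`.
#' Numeric values are written at full double precision (q-values therefore
#' carry well over 6 significant digits). Optional `header_lines` are
#' prepended as `#`-prefixed comments, which [read_results()] skips.
#'
#' @param r Data frame with the columns above (as returned by [run_emd_de()]).
#' @param path Output path.
#' @param header_lines Optional character vector of provenance comments.
#' @return Invisibly, `path`.
#' @export
write_results <- function(r, path, header_lines = NULL) {
  need <- c("gene", "score", "null_median", "q_value", "fold_change")
  miss <- setdiff(need, colnames(r))
  if (length(miss)) stop("result table lacks column(s): ", paste(miss, collapse = ", "))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(r[, need], con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read back a result table written by [write_results()]
#'
#' @param path Path to a result TSV (comment lines starting `#` are skipped).
#' @return Data frame with columns gene, score, null_median, q_value,
#'   fold_change.
#' @export
read_results <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

check_expression_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("expression data must be a numeric matrix")
  if (any(!is.finite(m))) stop("expression matrix contains non-finite values")
  invisible(m)
}
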