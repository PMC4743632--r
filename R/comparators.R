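#' Two-sample Kolmogorov-Smirnov statistic
#'
#' `D = sup_t |ECDF_x(t) - ECDF_y(t)|` with the asymptotic two-sample
#' p-value (Kolmogorov distribution at effective size `nm/(n+m)`), via
#' [stats::ks.test()]. KS is invariant under monotone transforms of both
#' samples and reacts only to the single largest CDF gap, which is why it
#' loses power against multi-modal within-class heterogeneity.
#'
#' @param x,y Non-empty numeric vectors.
#' @return List with `D` (in `[0, 1]`) and `p`.
#' @export
ks_statistic <- function(x, y) {
  if (!length(x) || !length(y)) stop("x and y must be non-empty")
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Two-sample Cramer-von Mises statistic (raw CDF-difference form)
#'
#' `W = sum_t (ECDF_x(t) - ECDF_y(t))^2` where `t` ranges over every pooled
#' observation (per occurrence: tied observations each contribute a term,
#' with the ECDFs evaluated at their common value). This is the plain sum of
#' squared CDF differences, not the classical `nm/(n+m)^2`-normalized
#' variant; its significance comes from the same permutation machinery as
#' the EMD score, which is insensitive to the fixed scale factor.
#'
#' @param x,y Non-empty numeric vectors.
#' @return Nonnegative scalar `W`.
#' @export
cvm_statistic <- function(x, y) {
  if (!length(x) || !length(y)) stop("x and y must be non-empty")
  pooled <- c(x, y)
  dif <- stats::ecdf(x)(pooled) - stats::ecdf(y)(pooled)
  sum(dif * dif)
}

#' SAM-style moderated t-statistic
#'
#' `d_j = (mean_2j - mean_1j) / (s_j + s0)` per gene, where `s_j` is the
#' pooled standard error of the equal-variance two-sample t-statistic and
#' the fudge factor `s0` damps the inflation of `d` for low-variance genes.
#' `s0` defaults to the median of the `s_j` over genes (a simplification of
#' SAM's coefficient-of-variation grid search that keeps the statistic's
#' qualitative behavior). With `s0 = 0`, `d` is exactly the ordinary
#' equal-variance t-statistic (up to the mean-difference sign convention:
#' class 2 minus class 1).
#'
#' @param m Numeric genes x samples matrix.
#' @param labels Two-class labels; both classes need >= 2 samples.
#' @param s0 Fudge factor; `NULL` (default) uses `median(s_j)`.
#' @param classes Optional length-2 vector fixing class order.
#' @return Named numeric vector of signed `d` values, with the `s0` used
#'   attached as attribute `"s0"`.
#' @export
sam_d_statistic <- function(m, labels, s0 = NULL, classes = NULL) {
  check_expression_matrix(m)
  labels <- pair_labels(m, labels, classes = classes)
  z <- as.numeric(labels == levels(labels)[1L])
  n1 <- sum(z); n2 <- sum(1 - z)
  if (n1 < 2L || n2 < 2L) stop("each class needs at least 2 samples")
  prep <- sam_engine_prepare(m)
  if (is.null(s0)) s0 <- stats::median(sam_engine_scores(prep, z, n1, n2, 0)$s)
  res <- sam_engine_scores(prep, z, n1, n2, s0)
  if (s0 == 0 && any(res$s == 0)) {
    stop("zero-variance gene with s0 = 0: d undefined")
  }
  structure(stats::setNames(res$d, rownames(m)), s0 = s0)
}

#' Run a baseline comparator genome-wide
#'
#' Applies one of the comparison statistics to every gene and attaches
#' significance: BH-adjusted asymptotic p-values for KS, or permutation
#' q-values (via [permuted_null()] + [fdr_grid()], on `|statistic|`) for CVM
#' and the SAM-style d — the same machinery used for the EMD score, so the
#' methods are directly comparable.
#'
#' @inheritParams run_emd_de
#' @param method `"ks"`, `"cvm"` or `"sam"`.
#' @return A data frame with one row per gene: `gene`, `statistic` (KS D,
#'   CVM W, or signed SAM d), `null_median` (`NA` for KS) and `significance`
#'   (adjusted p for KS, permutation q otherwise), with attribute
#'   `"method"`.
#' @export
run_comparator <- function(m, labels, method = c("ks", "cvm", "sam"),
                           classes = NULL, n_perm = 1000, seed = 1,
                           delta = 0.001, tmax = NULL) {
  check_expression_matrix(m)
  method <- match.arg(method)
  labels <- pair_labels(m, labels, classes = classes)
  z <- as.integer(labels == levels(labels)[1L])
  n1 <- sum(z); n2 <- sum(1 - z)
  genes <- if (is.null(rownames(m))) as.character(seq_len(nrow(m))) else rownames(m)

  if (method == "ks") {
    idx1 <- which(z == 1L)
    stat <- numeric(nrow(m)); pval <- numeric(nrow(m))
    for (g in seq_len(nrow(m))) {
      ks <- ks_statistic(m[g, idx1], m[g, -idx1])
      stat[g] <- ks$D; pval[g] <- ks$p
    }
    sig <- bh_adjust(pval)
    null_med <- rep(NA_real_, nrow(m))
  } else if (method == "cvm") {
    stat <- engine_observed(m, z, n1, n2, "cvm", bin_width = NULL)
    null <- permuted_null(m, labels, stat = "cvm", n_perm = n_perm, seed = seed)
    sig <- fdr_grid(stat, null, delta = delta, tmax = tmax)$qvalues
    null_med <- null$medians
  } else {
    d <- sam_d_statistic(m, labels)
    null <- permuted_null(m, labels, stat = "sam", n_perm = n_perm,
                          seed = seed, s0 = attr(d, "s0"))
    sig <- fdr_grid(abs(d), null, delta = delta, tmax = tmax)$qvalues
    null_med <- null$medians
    stat <- as.numeric(d)
  }
  structure(data.frame(gene = genes, statistic = unname(stat),
                       null_median = unname(null_med),
                       significance = unname(sig),
                       stringsAsFactors = FALSE),
            method = method)
}
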