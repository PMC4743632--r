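# Deterministic substream seeds, so e.g. changing n_perm never perturbs the
# bootstrap draws. Doubles are exact here (< 2^53) and results stay < 2^31.
derive_seed <- function(seed, stream = c("perm", "boot", "sim", "sweep")) {
  stream <- match.arg(stream)
  offset <- c(perm = 101L, boot = 202L, sim = 303L, sweep = 404L)[[stream]]
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

#' Per-gene median of label-permuted scores
#'
#' Generates the empirical null for the FDR computation: in each iteration
#' the class labels are randomly reassigned over all samples (class sizes
#' preserved, one shared relabeling for every gene), the two-sample
#' statistic is recomputed genome-wide, and the per-gene median over all
#' iterations is returned. Built-in statistics (`"emd"`, `"cvm"`, `"sam"`)
#' use vectorized engines; alternatively `stat` may be any function with the
#' [emd_score()] signature `(x, y) -> score`, applied gene by gene (slow,
#' intended for small data and cross-checks).
#'
#' Genes are processed in blocks against a shared permutation index matrix,
#' so memory stays at O(block x n_perm) scores beyond the per-iteration pass.
#'
#' @param m Numeric genes x samples expression matrix.
#' @param labels Two-class labels (named factor/character, see
#'   [as_class_labels()]).
#' @param stat `"emd"`, `"cvm"`, `"sam"`, or a `function(x, y)` returning a
#'   scalar score. Default `"emd"`.
#' @param n_perm Number of label permutations. Default 1000.
#' @param seed Integer seed; the same seed reproduces the null exactly.
#' @param bin_width Histogram bin width for the EMD statistic. Default 0.2.
#' @param s0 Fudge factor for `stat = "sam"`; defaults to the value computed
#'   from the observed labeling (held fixed across permutations).
#' @param block_genes Genes per processing block. Default scales with
#'   `n_perm` to bound the score buffer.
#' @return An object of class `perm_null`: list with `medians` (named
#'   per-gene vector), `n_perm`, `stat` and `seed`.
#' @export
permuted_null <- function(m, labels, stat = "emd", n_perm = 1000, seed = 1,
                          bin_width = 0.2, s0 = NULL, block_genes = NULL) {
  check_expression_matrix(m)
  if (!is.numeric(n_perm) || n_perm < 1) stop("n_perm must be >= 1")
  n_perm <- as.integer(n_perm)
  labels <- pair_labels(m, labels)
  z <- as.integer(labels == levels(labels)[1L])
  n1 <- sum(z); n2 <- sum(1 - z); ns <- ncol(m)
  if (n1 < 2L || n2 < 2L) stop("each class needs at least 2 samples")
  if (is.null(block_genes)) block_genes <- max(1L, as.integer(4e6 / n_perm))

  withr::local_seed(derive_seed(seed, "perm"))
  perm_idx <- replicate(n_perm, sample.int(ns, n1))   # n1 x n_perm

  is_fun <- is.function(stat)
  if (!is_fun) {
    stat <- match.arg(stat, c("emd", "cvm", "sam"))
    if (stat == "sam" && is.null(s0)) {
      prep0 <- sam_engine_prepare(m)
      s0 <- stats::median(sam_engine_scores(prep0, z, n1, n2, 0)$s)
    }
  }

  n_genes <- nrow(m)
  medians <- numeric(n_genes)
  for (start in seq(1L, n_genes, by = block_genes)) {
    rows <- start:min(start + block_genes - 1L, n_genes)
    xb <- m[rows, , drop = FALSE]
    scores <- matrix(0, length(rows), n_perm)
    if (is_fun) {
      for (p in seq_len(n_perm)) {
        i1 <- perm_idx[, p]
        for (g in seq_along(rows)) {
          scores[g, p] <- stat(xb[g, i1], xb[g, -i1])
        }
      }
    } else if (stat == "emd") {
      prep <- emd_engine_prepare(xb, bin_width)
      for (p in seq_len(n_perm)) {
        scores[, p] <- emd_engine_scores(prep, perm_idx[, p], n1, n2)
      }
    } else if (stat == "cvm") {
      prep <- cvm_engine_prepare(xb)
      for (p in seq_len(n_perm)) {
        zp <- integer(ns); zp[perm_idx[, p]] <- 1L
        scores[, p] <- cvm_engine_scores(prep, zp, n1, n2)
      }
    } else {
      prep <- sam_engine_prepare(xb)
      for (p in seq_len(n_perm)) {
        zp <- numeric(ns); zp[perm_idx[, p]] <- 1
        scores[, p] <- abs(sam_engine_scores(prep, zp, n1, n2, s0)$d)
      }
    }
    medians[rows] <- apply(scores, 1L, stats::median)
  }
  names(medians) <- rownames(m)
  structure(list(medians = medians, n_perm = n_perm,
                 stat = if (is_fun) "custom" else stat, seed = seed, s0 = s0),
            class = "perm_null")
}

#' FDR grid and q-values from a median-permutation null
#'
#' Given observed per-gene scores and the per-gene medians `M` of the
#' permuted scores, evaluates a grid of significance thresholds `t_i`
#' descending from `T` to 0 in steps of `delta`. At threshold `t_i` the FDR
#' for gene j is
#' `sum_k I(m_k > t_i) / sum_k I(score_k > t_i)` when `score_j >= t_i`, and
#' 1 otherwise; ratios are capped at 1 (and a threshold exceeded by no
#' observed score is uninformative: FDR 1). The q-value of gene j is the
#' minimum of its FDRs over the grid.
#'
#' @param obs Numeric vector of observed nonnegative scores.
#' @param null A `perm_null` object or numeric vector of null medians, same
#'   length as `obs`.
#' @param delta Threshold spacing. Default 0.001.
#' @param tmax Top threshold `T`. Default `round(max(obs)) - 1`, floored at
#'   `delta` so that low-score datasets still get a grid.
#' @param keep_matrix If `TRUE`, also return the dense genes x thresholds
#'   FDR matrix (memory heavy; diagnostics only).
#' @return An object of class `fdr_grid`: list with `thresholds`
#'   (descending), `null_exceed` and `obs_exceed` counts per threshold,
#'   `fdr` (capped ratio per threshold), `qvalues` (named like `obs`),
#'   `tmax`, `delta`, and optionally `fdr_matrix`.
#' @export
fdr_grid <- function(obs, null, delta = 0.001, tmax = NULL,
                     keep_matrix = FALSE) {
  if (inherits(null, "perm_null")) null <- null$medians
  if (!length(obs)) stop("empty score vector")
  if (length(obs) != length(null)) stop("obs and null lengths differ")
  if (any(!is.finite(obs)) || any(!is.finite(null))) stop("scores must be finite")
  if (!is.numeric(delta) || delta <= 0) stop("delta must be > 0")
  if (is.null(tmax)) tmax <- max(round(max(obs)) - 1, delta)
  if (tmax <= 0) stop("tmax must be > 0")

  k <- ceiling(tmax / delta - 1e-9)
  thr <- c(tmax - delta * (0:(k - 1)), 0)       # descending, last exactly 0
  nt <- length(thr)

  ms <- sort(null); os <- sort(obs)
  n_null_exceed <- length(null) - findInterval(thr, ms)   # I(m_k > t), strict
  n_obs_exceed <- length(obs) - findInterval(thr, os)     # I(score_k > t), strict
  ratio <- ifelse(n_obs_exceed == 0, 1, pmin(n_null_exceed / n_obs_exceed, 1))

  suffix_min <- rev(cummin(rev(ratio)))
  thr_asc <- rev(thr)
  pos <- findInterval(obs, thr_asc)             # thresholds with t <= obs
  q <- suffix_min[nt - pos + 1L]
  names(q) <- names(obs)

  out <- structure(list(thresholds = thr, null_exceed = n_null_exceed,
                        obs_exceed = n_obs_exceed, fdr = ratio,
                        qvalues = q, tmax = tmax, delta = delta),
                   class = "fdr_grid")
  if (keep_matrix) {
    fm <- matrix(1, length(obs), nt,
                 dimnames = list(names(obs), NULL))
    for (i in seq_len(nt)) {
      appl <- obs >= thr[i]
      fm[appl, i] <- ratio[i]
    }
    out$fdr_matrix <- fm
  }
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values via [stats::p.adjust()], with input validation.
#' Used for the KS comparator, whose p-values are analytic rather than
#' permutation based.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (monotone, capped at 1), same names as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Genome-wide EMD differential-distribution analysis
#'
#' The full pipeline for one expression matrix: per-gene EMD score between
#' the two classes, label-permutation null ([permuted_null()]), q-values
#' from the FDR grid ([fdr_grid()]), and per-gene fold change.
#'
#' @inheritParams permuted_null
#' @param classes Optional length-2 vector fixing which class is "class 1"
#'   (fold-change denominator).
#' @param delta,tmax FDR grid parameters, see [fdr_grid()].
#' @param fc_scale `"log2"` (values are log-scale; fold change is
#'   `2^(mean2 - mean1)`) or `"linear"` (ratio of class means). Default
#'   `"log2"`.
#' @return A data frame with one row per gene: `gene`, `score` (observed
#'   EMD), `null_median`, `q_value`, `fold_change`.
#' @examples
#' sim <- simulate_case(builtin_case(1, n_genes = 60, n_de = 10,
#'                                   n1 = 20, n2 = 30, seed = 7))
#' res <- run_emd_de(sim$expression, sim$labels, n_perm = 50, seed = 7)
#' head(res[order(res$q_value), ])
#' @export
run_emd_de <- function(m, labels, classes = NULL, bin_width = 0.2,
                       n_perm = 1000, seed = 1, delta = 0.001, tmax = NULL,
                       fc_scale = c("log2", "linear")) {
  check_expression_matrix(m)
  fc_scale <- match.arg(fc_scale)
  labels <- pair_labels(m, labels, classes = classes)
  z <- as.integer(labels == levels(labels)[1L])
  n1 <- sum(z); n2 <- sum(1 - z)
  obs <- engine_observed(m, z, n1, n2, "emd", bin_width)
  names(obs) <- rownames(m)
  null <- permuted_null(m, labels, stat = "emd", n_perm = n_perm,
                        seed = seed, bin_width = bin_width)
  grid <- fdr_grid(obs, null, delta = delta, tmax = tmax)
  data.frame(gene = if (is.null(rownames(m))) seq_len(nrow(m)) else rownames(m),
             score = unname(obs),
             null_median = unname(null$medians),
             q_value = unname(grid$qvalues),
             fold_change = unname(fold_change(m, labels, scale = fc_scale)),
             stringsAsFactors = FALSE)
}

#' Bootstrap stability of significance calls
#'
#' Resamples samples with replacement within each class (class sizes
#' preserved), reruns the chosen method, and records q-values across
#' iterations. Summarizes how stable the significant-gene set is: the
#' per-gene median q-value across iterations, and the number of genes below
#' the significance threshold in each iteration.
#'
#' @inheritParams run_emd_de
#' @param method `"emd"`, `"cvm"`, `"sam"` (permutation q-values) or `"ks"`
#'   (BH-adjusted p-values).
#' @param n_boot Number of bootstrap iterations. Default 100.
#' @param q_threshold Significance cutoff counted per iteration. Default 0.05.
#' @param ... Passed to [run_emd_de()] / [run_comparator()] (e.g. `n_perm`,
#'   `bin_width`).
#' @return An object of class `boot_stability`: list with `median_q` (named
#'   per-gene vector), `sig_counts` (length `n_boot`), `n_boot`,
#'   `q_threshold`, `method`.
#' @export
bootstrap_stability <- function(m, labels, method = "emd", n_boot = 100,
                                seed = 1, q_threshold = 0.05, ...) {
  check_expression_matrix(m)
  if (!is.numeric(n_boot) || n_boot < 1) stop("n_boot must be >= 1")
  n_boot <- as.integer(n_boot)
  labels <- pair_labels(m, labels)
  idx_by_class <- split(seq_len(ncol(m)), labels)

  withr::local_seed(derive_seed(seed, "boot"))
  iter_seeds <- sample.int(2147483647L - 1L, n_boot)
  draws <- lapply(seq_len(n_boot), function(b) {
    unlist(lapply(idx_by_class, function(ix) sample(ix, length(ix), replace = TRUE)),
           use.names = FALSE)
  })

  qmat <- matrix(NA_real_, nrow(m), n_boot)
  sig_counts <- integer(n_boot)
  for (b in seq_len(n_boot)) {
    cols <- draws[[b]]
    mb <- m[, cols, drop = FALSE]
    colnames(mb) <- make.unique(colnames(m)[cols])
    lb <- stats::setNames(as.character(labels)[cols], colnames(mb))
    lb <- as_class_labels(lb, classes = levels(labels))
    qb <- if (method == "emd") {
      run_emd_de(mb, lb, seed = iter_seeds[b], ...)$q_value
    } else {
      run_comparator(mb, lb, method = method, seed = iter_seeds[b], ...)$significance
    }
    qmat[, b] <- qb
    sig_counts[b] <- sum(qb < q_threshold)
  }
  structure(list(median_q = stats::setNames(apply(qmat, 1L, stats::median),
                                            rownames(m)),
                 sig_counts = sig_counts, n_boot = n_boot,
                 q_threshold = q_threshold, method = method),
            class = "boot_stability")
}
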