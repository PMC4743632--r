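# Internal vectorized engines for genome-wide statistics under many label
# permutations. All three share the same layout: a one-time prepare step per
# gene block, then a cheap per-permutation pass made of whole-vector
# operations (tabulate / cumsum / rowsum), so the label-permutation loop
# never touches individual genes.

# --- EMD ---------------------------------------------------------------
# Each gene gets its own grid (built from all samples pooled, so it is valid
# for every relabeling); bins of all genes are concatenated into one global
# index space. For a gene segment, counts1/n1 - counts2/n2 sums to zero, so
# a single global cumsum restarts at each segment boundary by itself and the
# per-gene score is bin_width * segment-sum of |cumsum|.

emd_engine_prepare <- function(X, bin_width) {
  n_genes <- nrow(X); n_samp <- ncol(X)
  lo <- apply(X, 1L, min)
  hi <- apply(X, 1L, max)
  k <- pmax(1, ceiling((hi - lo) / bin_width - 1e-9) + 1)
  off <- c(0, cumsum(k))[seq_len(n_genes)]
  bi <- floor((X - lo) / bin_width + 0.5) + 1   # lo recycles down columns
  bi <- pmin(pmax(bi, 1), k)                    # guard float edge cases
  gb <- t(bi + off)                             # samples x genes, global bin ids
  storage.mode(gb) <- "integer"
  total_bins <- sum(k)
  list(gb = gb, total_bins = total_bins,
       tot = tabulate(gb, nbins = total_bins),
       seg = rep.int(seq_len(n_genes), k),
       bin_width = bin_width, n_samp = n_samp)
}

# idx1: column indices (samples) assigned to class 1
emd_engine_scores <- function(prep, idx1, n1, n2) {
  counts1 <- tabulate(prep$gb[idx1, ], nbins = prep$total_bins)
  d <- counts1 / n1 - (prep$tot - counts1) / n2
  cs <- cumsum(d)
  prep$bin_width * as.vector(rowsum(abs(cs), prep$seg, reorder = FALSE))
}

# --- Cramer-von Mises --------------------------------------------------
# Values of each gene are pre-sorted once; for a relabeling, the ECDF
# difference at the t-th pooled point is the cumsum of z/n1 - (1-z)/n2 over
# the sorted order (z = class-1 indicator). Each gene segment again sums to
# zero. Ties are handled by reading the cumsum at the last index of each
# tied run, so every pooled occurrence contributes the ECDF difference
# evaluated at its value.

cvm_engine_prepare <- function(X) {
  n_genes <- nrow(X); n_samp <- ncol(X)
  sot <- apply(X, 1L, order)                    # samples x genes
  sv <- apply(X, 1L, sort)
  x <- as.vector(sv)
  len <- length(x)
  new_run <- c(TRUE, x[-1L] != x[-len])
  new_run[seq(1L, len, by = n_samp)] <- TRUE    # runs never cross genes
  run_id <- cumsum(new_run)
  run_last <- which(c(new_run[-1L], TRUE))      # last index of each run
  list(sot = sot, tie_last = run_last[run_id],
       seg = rep(seq_len(n_genes), each = n_samp),
       col_off = rep((seq_len(n_genes) - 1L) * n_samp, each = n_samp),
       n_samp = n_samp)
}

# z: 0/1 class-1 indicator over samples
cvm_engine_scores <- function(prep, z, n1, n2) {
  v <- z[as.vector(prep$sot)] * (1 / n1 + 1 / n2) - 1 / n2
  cs <- cumsum(v)[prep$tie_last]
  as.vector(rowsum(cs * cs, prep$seg, reorder = FALSE))
}

# --- moderated t (SAM-style d) -----------------------------------------
# Class means and pooled standard errors for every gene at once via two
# matrix-vector products per class.

sam_engine_prepare <- function(X) {
  list(X = X, X2 = X * X)
}

# returns list(d, s): signed d-statistic and the per-gene standard error s_j
sam_engine_scores <- function(prep, z, n1, n2, s0) {
  z2 <- 1 - z
  sum1 <- as.vector(prep$X %*% z);  sum2 <- as.vector(prep$X %*% z2)
  ss1 <- as.vector(prep$X2 %*% z);  ss2 <- as.vector(prep$X2 %*% z2)
  m1 <- sum1 / n1; m2 <- sum2 / n2
  sp2 <- (ss1 - n1 * m1^2 + ss2 - n2 * m2^2) / (n1 + n2 - 2)
  sp2[sp2 < 0] <- 0                             # numerical guard
  s <- sqrt((1 / n1 + 1 / n2) * sp2)
  d <- (m2 - m1) / (s + s0)
  d[s + s0 == 0 & m2 == m1] <- 0               # constant gene: no difference
  list(d = d, s = s)
}

# Dispatch: observed per-gene scores for a given statistic name.
# stat_fun, when given, is a function(x, y) -> score applied gene-wise.
engine_observed <- function(X, z, n1, n2, stat, bin_width, s0 = NULL) {
  idx1 <- which(z == 1)
  switch(stat,
    emd = emd_engine_scores(emd_engine_prepare(X, bin_width), idx1, n1, n2),
    cvm = cvm_engine_scores(cvm_engine_prepare(X), z, n1, n2),
    sam = abs(sam_engine_scores(sam_engine_prepare(X), z, n1, n2, s0)$d),
    stop("unknown statistic: ", stat)
  )
}
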