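# Shared fixture builders: everything is generated in code at test time.

# small labelled matrix with a known mean-shifted gene block
tiny_dataset <- function(n_genes = 40, n_de = 8, n1 = 12, n2 = 18,
                         shift = 5, seed = 402) {
  sim <- simulate_case(simulation_spec(
    n_genes = n_genes, n_de = n_de, n1 = n1, n2 = n2,
    de_class1 = data.frame(weight = 1, mean = shift, var = 1),
    de_class2_var = 1, de_class2_mean_var = 0.0001, seed = seed))
  sim
}

write_expression_tsv <- function(m, path, delimiter = "\t") {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  path
}

write_labels_tsv <- function(labels, path) {
  utils::write.table(data.frame(names(labels), as.character(labels)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  path
}

# random unit-mass signature on a given grid
random_signature <- function(grid, rng_n = 1) {
  k <- length(grid$centers)
  w <- stats::rexp(k)
  structure(list(centers = grid$centers, weights = w / sum(w),
                 width = grid$width),
            class = "emd_signature")
}

shared_grid <- function(k = 8, width = 0.2, origin = 0) {
  structure(list(centers = origin + width * (seq_len(k) - 1), width = width),
            class = "bin_grid")
}

# brute-force two-sample statistics: direct sup / double loop over pooled
# evaluation points
brute_ks_D <- function(x, y) {
  pooled <- c(x, y)
  max(abs(vapply(pooled, function(t) mean(x <= t) - mean(y <= t), 0)))
}

brute_cvm_W <- function(x, y) {
  s <- 0
  for (t in c(x, y)) {
    fx <- sum(x <= t) / length(x)
    fy <- sum(y <= t) / length(y)
    s <- s + (fx - fy)^2
  }
  s
}

# independent brute-force FDR-grid oracle: materializes the full
# genes x thresholds FDR matrix directly from the printed formula
brute_fdr_q <- function(obs, med, delta, tmax) {
  k <- ceiling(tmax / delta - 1e-9)
  thr <- c(tmax - delta * (0:(k - 1)), 0)
  q <- numeric(length(obs))
  for (j in seq_along(obs)) {
    fdr_j <- rep(1, length(thr))
    for (i in seq_along(thr)) {
      if (obs[j] >= thr[i]) {
        num <- sum(med > thr[i])
        den <- sum(obs > thr[i])
        fdr_j[i] <- if (den == 0) 1 else min(num / den, 1)
      }
    }
    q[j] <- min(fdr_j)
  }
  q
}
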