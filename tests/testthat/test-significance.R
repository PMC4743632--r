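test_that("permutation null is deterministic, zero for constant genes, and engine-consistent", {
  sim <- tiny_dataset(n_genes = 25, n_de = 5, n1 = 8, n2 = 10)
  m <- sim$expression
  m["g00020", ] <- 3.7                          # constant gene
  null1 <- permuted_null(m, sim$labels, n_perm = 40, seed = 9)
  null2 <- permuted_null(m, sim$labels, n_perm = 40, seed = 9)
  null3 <- permuted_null(m, sim$labels, n_perm = 40, seed = 10)
  expect_identical(null1$medians, null2$medians)
  expect_false(identical(null1$medians, null3$medians))
  expect_equal(unname(null1$medians["g00020"]), 0)
  expect_true(all(null1$medians >= 0))

  # the vectorized engine and a gene-wise custom function agree through the
  # whole permutation pipeline
  nullf <- permuted_null(m, sim$labels,
                         stat = function(x, y) emd_score(x, y, 0.2),
                         n_perm = 40, seed = 9)
  expect_equal(nullf$medians, null1$medians, tolerance = 1e-9)

  # block splitting does not change the result
  # block splitting changes only the accumulation order of the cumulative
  # sums, so results agree to float accumulation error
  nullb <- permuted_null(m, sim$labels, n_perm = 40, seed = 9, block_genes = 7)
  expect_equal(nullb$medians, null1$medians, tolerance = 1e-12)

  expect_error(permuted_null(m, sim$labels, n_perm = 0), "n_perm")
})

test_that("FDR grid reproduces the hand-enumerated example", {
  # at thresholds in [0.5, 2] only gene 1 exceeds and no null median does ->
  # FDR 0 for gene 1; for genes 2-3 every applicable ratio caps at 1
  g <- fdr_grid(c(3.0, 0.4, 0.3), c(0.5, 0.45, 0.35), delta = 0.1, tmax = 2)
  expect_equal(unname(g$qvalues), c(0, 1, 1))
  expect_equal(g$thresholds[1], 2)
  expect_equal(tail(g$thresholds, 1), 0)
  expect_equal(unique(round(-diff(g$thresholds), 12)), 0.1)

  # observed identical to null medians -> nothing is separable, all q = 1
  set.seed(3)
  v <- rexp(50)
  expect_true(all(fdr_grid(v, v, delta = 0.05)$qvalues == 1))

  expect_error(fdr_grid(numeric(0), numeric(0)), "empty")
  expect_error(fdr_grid(1, 1, delta = 0), "delta")
})

test_that("q-values are monotone in the observed score and match brute force", {
  set.seed(77)
  for (r in 1:25) {
    n <- sample(5:200, 1)
    obs <- rexp(n, rate = 1 / 2)
    med <- rexp(n, rate = 2)
    delta <- sample(c(0.01, 0.05, 0.1), 1)
    tmax <- max(round(max(obs)) - 1, delta)
    fast <- fdr_grid(obs, med, delta = delta, tmax = tmax)
    expect_equal(unname(fast$qvalues), brute_fdr_q(obs, med, delta, tmax),
                 tolerance = 0)
    # same null: a larger observed score never gets a larger q
    ord <- order(obs)
    expect_true(all(diff(fast$qvalues[ord]) <= 0))
  }

  # the optional dense matrix agrees with the q-values
  obs <- c(2.4, 0.3, 1.1); med <- c(0.4, 0.5, 0.3)
  g <- fdr_grid(obs, med, delta = 0.05, tmax = 2, keep_matrix = TRUE)
  expect_identical(dim(g$fdr_matrix), c(3L, length(g$thresholds)))
  expect_equal(apply(g$fdr_matrix, 1, min), unname(g$qvalues))
})

test_that("BH adjustment matches the step-up computation", {
  # hand BH: sorted p (0.01,0.02,0.03) * 3/(1,2,3) = (0.03,0.03,0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(8)
  p <- runif(30)
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(-0.1, 0.5)), "\\[0, 1\\]")
})

test_that("the full pipeline ranks shifted genes first and is gene-order equivariant", {
  sim <- tiny_dataset(n_genes = 30, n_de = 6, n1 = 10, n2 = 12, shift = 5)
  res <- run_emd_de(sim$expression, sim$labels, n_perm = 60, seed = 2)
  expect_identical(nrow(res), 30L)
  expect_true(all(res$q_value >= 0 & res$q_value <= 1))
  expect_identical(res$gene, rownames(sim$expression))
  # every strongly shifted gene beats every null gene
  expect_lt(max(res$q_value[sim$truth]), min(res$q_value[!sim$truth]) + 1e-12)

  # permuting gene rows permutes the result rows consistently
  perm <- sample(nrow(sim$expression))
  res2 <- run_emd_de(sim$expression[perm, ], sim$labels, n_perm = 60, seed = 2)
  expect_equal(res2$q_value, res$q_value[perm])
  expect_equal(res2$score, res$score[perm])
})

test_that("pure-null data yield calls at no more than the nominal rate", {
  frac05 <- frac20 <- numeric(3)
  for (r in 1:3) {
    sim <- simulate_case(simulation_spec(n_genes = 150, n_de = 0, n1 = 15,
                                         n2 = 20, seed = 600 + r))
    res <- run_emd_de(sim$expression, sim$labels, n_perm = 80, seed = r)
    frac05[r] <- mean(res$q_value < 0.05)
    frac20[r] <- mean(res$q_value < 0.20)
  }
  expect_lte(mean(frac05), 0.05)
  expect_lte(mean(frac20), 0.20)
})

test_that("bootstrap stability is reproducible and summarizes q-values", {
  sim <- tiny_dataset(n_genes = 20, n_de = 4, n1 = 8, n2 = 8, shift = 5)
  b1 <- bootstrap_stability(sim$expression, sim$labels, n_boot = 3,
                            seed = 4, n_perm = 30)
  b2 <- bootstrap_stability(sim$expression, sim$labels, n_boot = 3,
                            seed = 4, n_perm = 30)
  expect_identical(b1$median_q, b2$median_q)
  expect_identical(b1$sig_counts, b2$sig_counts)
  expect_length(b1$sig_counts, 3L)
  expect_true(all(b1$median_q >= 0 & b1$median_q <= 1))

  # a single iteration's median is that iteration's q-value vector
  b3 <- bootstrap_stability(sim$expression, sim$labels, n_boot = 1,
                            seed = 4, n_perm = 30)
  expect_length(b3$sig_counts, 1L)
  expect_identical(unname(b3$sig_counts[1]),
                   sum(b3$median_q < b3$q_threshold))

  expect_error(bootstrap_stability(sim$expression, sim$labels, n_boot = 0),
               "n_boot")
})
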