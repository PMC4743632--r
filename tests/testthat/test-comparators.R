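test_that("KS statistic matches hand ECDF evaluation and brute force", {
  expect_equal(ks_statistic(c(1, 2, 3), c(4, 5, 6))$D, 1.0)
  expect_equal(ks_statistic(c(1, 2, 3), c(1, 2, 3))$D, 0)
  # ECDFs cross by 0.5 at the jump points 1,2,3,4
  expect_equal(ks_statistic(c(1, 3), c(2, 4))$D, 0.5)

  set.seed(41)
  for (r in 1:30) {
    x <- sample(1:20, sample(3:40, 1), replace = TRUE)  # ties included
    y <- rnorm(sample(3:40, 1))
    expect_equal(ks_statistic(x, y)$D, brute_ks_D(x, y), tolerance = 1e-12)
  }
  expect_error(ks_statistic(numeric(0), 1), "non-empty")
})

test_that("CVM statistic is the per-occurrence sum of squared ECDF gaps", {
  expect_equal(cvm_statistic(1:5, 1:5), 0)
  # pooled points {0, 1}: gap 1 at 0, gap 0 at 1
  expect_equal(cvm_statistic(0, 1), 1.0)

  set.seed(42)
  for (r in 1:30) {
    x <- sample(1:15, sample(2:50, 1), replace = TRUE)
    y <- sample(1:15, sample(2:50, 1), replace = TRUE)
    expect_equal(cvm_statistic(x, y), brute_cvm_W(x, y), tolerance = 1e-12)
  }
})

test_that("rank statistics ignore monotone transforms; the EMD score does not", {
  set.seed(43)
  x <- rnorm(30); y <- rnorm(40, 1)
  tr <- function(v) exp(v)                     # strictly monotone
  expect_equal(ks_statistic(tr(x), tr(y))$D, ks_statistic(x, y)$D,
               tolerance = 1e-12)
  expect_equal(cvm_statistic(tr(x), tr(y)), cvm_statistic(x, y),
               tolerance = 1e-12)
  # the EMD score lives in expression units and must move
  expect_gt(abs(emd_score(tr(x), tr(y)) - emd_score(x, y)), 0.05)
})

test_that("moderated t-statistic matches the two-sample t at s0 = 0", {
  m <- rbind(g1 = c(1, 2, 3, 4, 6, 8),
             g2 = c(2, 3, 2, 2, 3, 2))
  colnames(m) <- paste0("s", 1:6)
  labels <- as_class_labels(setNames(rep(c("a", "b"), each = 3), colnames(m)))

  d <- sam_d_statistic(m, labels, s0 = 0)
  # hand computation: means 2 and 6, pooled var (2*1+2*4)/4 = 2.5,
  # se = sqrt(2.5 * 2/3), d = 4 / 1.2909944 = 3.0983867
  expect_equal(unname(d["g1"]), 3.0983867, tolerance = 1e-6)
  expect_equal(unname(d["g2"]), 0)   # equal class means -> d = 0

  # zero-variance gene is undefined without the fudge factor
  mz <- rbind(g1 = c(1, 2, 3, 4, 6, 8), flatline = rep(2, 6))
  colnames(mz) <- colnames(m)
  expect_error(sam_d_statistic(mz, labels, s0 = 0), "zero-variance")
  # cross-check against the standard equal-variance t (opposite sign
  # convention: class 2 minus class 1)
  tt <- t.test(m["g1", 1:3], m["g1", 4:6], var.equal = TRUE)
  expect_equal(unname(d["g1"]), -unname(tt$statistic), tolerance = 1e-9)

  # equal mean difference, 4x the variance -> smaller |d|
  set.seed(44)
  base <- rnorm(20)
  m2 <- rbind(quiet = c(base, base + 2),
              noisy = c(2 * base, 2 * base + 2))
  colnames(m2) <- paste0("s", 1:40)
  lab2 <- as_class_labels(setNames(rep(c("a", "b"), each = 20), colnames(m2)))
  d2 <- sam_d_statistic(m2, lab2, s0 = 0)
  expect_lt(abs(d2["noisy"]), abs(d2["quiet"]))

  # default s0 is the median standard error and damps low-variance genes
  d3 <- sam_d_statistic(m2, lab2)
  expect_gt(attr(d3, "s0"), 0)
  expect_lt(abs(d3["quiet"]), abs(d2["quiet"]))
})

test_that("comparators run genome-wide with the appropriate significance", {
  sim <- tiny_dataset(n_genes = 30, n_de = 6, n1 = 10, n2 = 12, shift = 5)

  ks <- run_comparator(sim$expression, sim$labels, "ks")
  expect_identical(attr(ks, "method"), "ks")
  expect_true(all(ks$significance >= 0 & ks$significance <= 1))
  expect_true(all(ks$statistic >= 0 & ks$statistic <= 1))
  # significance is monotone in D at fixed sample sizes
  ord <- order(ks$statistic, decreasing = TRUE)
  expect_true(all(diff(ks$significance[ord]) >= -1e-12))

  cvm <- run_comparator(sim$expression, sim$labels, "cvm", n_perm = 50, seed = 3)
  sam <- run_comparator(sim$expression, sim$labels, "sam", n_perm = 50, seed = 3)
  expect_true(all(cvm$statistic >= 0))
  expect_true(all(cvm$significance >= 0 & cvm$significance <= 1))
  expect_true(all(sam$significance >= 0 & sam$significance <= 1))

  # all three methods rank the strongly shifted genes above the null genes
  # (by statistic; permutation q-values tie at 0 for such strong shifts)
  for (res in list(ks, cvm, sam)) {
    expect_gt(min(abs(res$statistic[sim$truth])),
              max(abs(res$statistic[!sim$truth])))
  }
  expect_error(run_comparator(sim$expression, sim$labels, "limma"))
})
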