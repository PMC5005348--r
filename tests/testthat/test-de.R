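test_that("size factors follow the median-of-ratios definition", {
  m <- matrix(c(5L, 8L, 12L, 5L, 8L, 12L), 3, 2,
              dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  expect_equal(unname(estimate_size_factors(m)), c(1, 1))

  m2 <- matrix(c(10L, 30L, 50L, 20L, 60L, 100L), 3, 2,
               dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  expect_equal(unname(estimate_size_factors(m2)),
               c(1 / sqrt(2), sqrt(2)))

  # odd gene count: the median is an order statistic, so the ratio-scale
  # oracle and the log-scale implementation must agree exactly
  set.seed(5)
  for (i in 1:10) {
    m3 <- matrix(sample(1:500, 204, TRUE), 51, 4,
                 dimnames = list(sprintf("G%02d", 1:51), sprintf("s%d", 1:4)))
    expect_equal(unname(estimate_size_factors(m3)),
                 oracle_size_factors(m3))
  }

  all_zero_somewhere <- matrix(c(0L, 3L, 2L, 0L), 2, 2,
                               dimnames = list(c("A", "B"), c("s1", "s2")))
  expect_error(estimate_size_factors(all_zero_somewhere),
               "pseudo-reference")
})

test_that("dispersion fit pools within condition and takes the max", {
  # gene with variance < mean: raw 0, final from the fitted curve
  set.seed(8)
  sim <- simulate_counts(n_genes = 500, n_reps = 5, de_fraction = 0,
                         dispersion = c(a0 = 0.1, a1 = 0), seed = 8)
  fit <- fit_dispersions(sim$counts)
  underdispersed <- which(fit$raw == 0)
  expect_gt(length(underdispersed), 0)
  expect_equal(fit$final[underdispersed], fit$fitted[underdispersed])
  expect_true(all(fit$final > 0))

  # Poisson data: fitted dispersions near zero
  psim <- simulate_counts(n_genes = 2000, n_reps = 5, de_fraction = 0,
                          dispersion = c(0, 0), seed = 9)
  expect_lt(median(fit_dispersions(psim$counts)$final), 0.05)

  const <- count_matrix(matrix(5L, 4, 4,
                               dimnames = list(paste0("g", 1:4),
                                               paste0("s", 1:4))),
                        setNames(rep(c("a", "b"), each = 2),
                                 paste0("s", 1:4)))
  expect_error(fit_dispersions(const), "constant")
})

test_that("the fitted dispersion intercept recovers a constant alpha", {
  sim <- simulate_counts(n_genes = 5000, n_reps = 10, de_fraction = 0,
                         mean_sampler = function(n) rlnorm(n, log(200), 1),
                         dispersion = c(a0 = 0.2, a1 = 0),
                         size_factors = rep(1, 20), seed = 12)
  fit <- fit_dispersions(sim$counts)
  # moment estimator carries a small finite-replicate bias; 0.03 covers
  # 3 Monte-Carlo SEs plus that bias at r = 10
  expect_lt(abs(fit$coef[["a0"]] - 0.2), 0.03)
})

test_that("exact test honours its symmetries and limits", {
  expect_equal(nb_exact_test(17, 17, c(1, 1), c(1, 1), 0.2), 1)
  # exchanging conditions (with their size factors) leaves p unchanged
  p1 <- nb_exact_test(5, 30, c(0.8, 1.1), c(1.0, 1.4), 0.15)
  p2 <- nb_exact_test(30, 5, c(1.0, 1.4), c(0.8, 1.1), 0.15)
  expect_equal(p1, p2)
  expect_equal(nb_exact_test(0, 0, 1, 1, 0.1), 1)

  # Poisson limit: conditional binomial two-sided test
  binom_cond <- function(kA, kB, prob) {
    d <- dbinom(0:(kA + kB), kA + kB, prob)
    sum(d[d <= d[kA + 1] * (1 + 1e-7)])
  }
  for (case in list(c(5, 15), c(2, 9), c(10, 10), c(0, 7))) {
    expect_equal(nb_exact_test(case[1], case[2], c(1, 1), c(1, 1), 1e-8),
                 binom_cond(case[1], case[2], 0.5), tolerance = 1e-3)
  }
  # unequal library sizes shift the conditional split accordingly
  expect_equal(nb_exact_test(6, 14, 1, 2, 1e-8),
               binom_cond(6, 14, 1 / 3), tolerance = 1e-3)

  expect_error(nb_exact_test(3, 4, 1, 1, 0), "positive")
  expect_error(nb_exact_test(Inf, 4, 1, 1, 0.1), "finite")
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(2)
  p <- runif(50)
  expect_true(all(adjust_bh(p) >= p))
  expect_true(all(adjust_bh(p) <= 1))
})

test_that("differential-expression summary counts and splits correctly", {
  res <- data.frame(gene = c("A", "B", "C", "D"),
                    log2fc = c(-2, 1, 0.3, -0.2),
                    padj = c(0.01, 0.04, 0.2, 0.9))
  s <- de_summary(res)
  expect_equal(s$n_de, 2)
  expect_equal(s$n_down + s$n_up, s$n_de)
  expect_equal(s$pct_de, 50)
  expect_identical(s$down_genes, "A")
  expect_identical(s$up_genes, "B")  # |log2fc| = 1 >= log2(1.5)

  none <- data.frame(gene = "A", log2fc = 0.1, padj = 0.9)
  s0 <- de_summary(none)
  expect_equal(c(s0$n_de, s0$n_down, s0$n_up, s0$pct_de), c(0, 0, 0, 0))
})

test_that("relabelling conditions negates fold changes, keeps p-values", {
  sim <- simulate_counts(n_genes = 300, seed = 33)
  r1 <- run_de(sim$counts, baseline = "presenescent")
  r2 <- run_de(sim$counts, baseline = "senescent")
  expect_equal(r1$log2fc, -r2$log2fc)
  expect_equal(r1$pval, r2$pval)
})

test_that("PCA separates planted condition structure", {
  base <- matrix(rpois(4000, 80), 1000, 4,
                 dimnames = list(sprintf("G%04d", 1:1000),
                                 c("a1", "a2", "b1", "b2")))
  base[1:200, c("b1", "b2")] <- base[1:200, c("b1", "b2")] + 300L
  cm <- count_matrix(base, c(a1 = "a", a2 = "a", b1 = "b", b2 = "b"))
  p <- pca_samples(cm)
  expect_gt(p$var_frac[1], 0.9)
  pc1 <- setNames(p$coords$PC1, p$coords$sample)
  expect_true(prod(range(pc1[c("a1", "a2")])) > 0 ||
                prod(range(pc1[c("b1", "b2")])) > 0)
  expect_true(max(pc1[c("a1", "a2")]) < min(pc1[c("b1", "b2")]) ||
                min(pc1[c("a1", "a2")]) > max(pc1[c("b1", "b2")]))

  same <- count_matrix(matrix(5L, 3, 3,
                              dimnames = list(paste0("g", 1:3),
                                              paste0("s", 1:3))))
  d <- pca_samples(same)
  expect_true(d$degenerate)
  expect_equal(sum(d$var_frac), 0)

  sim <- simulate_counts(n_genes = 2000, seed = 40,
                         lfc_sampler = function(n)
                           sample(c(-2, 2), n, TRUE))
  ps <- pca_samples(sim$counts)
  cond <- ps$coords$condition
  expect_true(max(ps$coords$PC1[cond == cond[1]]) <
                min(ps$coords$PC1[cond != cond[1]]) ||
              min(ps$coords$PC1[cond == cond[1]]) >
                max(ps$coords$PC1[cond != cond[1]]))
})

test_that("replicate correlation behaves as a similarity measure", {
  m <- matrix(rpois(200, 50), 100, 2,
              dimnames = list(sprintf("G%03d", 1:100), c("r1", "r2")))
  m[, 2] <- m[, 1]
  cm <- count_matrix(m)
  expect_equal(unname(replicate_r2(cm, pairs = list(c("r1", "r2")))), 1)

  # independent Poisson replicates still correlate via shared means
  sim <- simulate_counts(n_genes = 5000, n_reps = 2, de_fraction = 0,
                         dispersion = c(0, 0), seed = 50)
  r2 <- replicate_r2(sim$counts)
  expect_true(all(r2 > 0.9))

  # r^2 equals squared Pearson r computed directly
  lm1 <- log2(sweep(sim$counts$counts, 2,
                    estimate_size_factors(sim$counts), "/") + 1)
  keep <- rowSums(sim$counts$counts) > 0
  direct <- oracle_pearson(lm1[keep, 1], lm1[keep, 2])^2
  expect_equal(unname(r2[1]), direct, tolerance = 1e-12)

  expect_error(
    replicate_r2(sim$counts,
                 pairs = list(c("presenescent_1", "senescent_1"))),
    "spans two conditions")
})

test_that("fold-change estimates recover strong planted signals", {
  sim <- simulate_counts(n_genes = 500, n_reps = 5, de_fraction = 0.2,
                         lfc_sampler = function(n) sample(c(-2, 2), n, TRUE),
                         mean_sampler = function(n) 100 * 2^runif(n, 0, 3),
                         seed = 60)
  res <- run_de(sim$counts)
  idx <- match(sim$truth$de_genes, res$gene)
  mae <- mean(abs(res$log2fc[idx] - sim$truth$lfc[sim$truth$de_genes]))
  expect_lt(mae, 0.25)
  # strong DE genes are overwhelmingly detected
  expect_gt(mean(res$padj[idx] < 0.05), 0.9)
})

test_that("the exact test controls the false positive rate on null data", {
  fdp <- vapply(1:20, function(s) {
    sim <- simulate_counts(n_genes = 1000, n_reps = 2, de_fraction = 0,
                           seed = 1000 + s)
    res <- run_de(sim$counts)
    mean(res$padj < 0.05, na.rm = TRUE)
  }, numeric(1))
  mc_se <- sd(fdp) / sqrt(length(fdp))
  expect_lte(mean(fdp), 0.05 + 3 * mc_se)
})
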