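# Simulation generators: marginal rates, determinism, dependence structure.

test_that("non-null p-values follow the two-sided Beta mixture", {
  set.seed(101)
  p <- sample_nonnull_p(100, 1e5)
  expect_true(all(p > 0 & p < 1))
  expect_equal(mean(p), 0.5, tolerance = 0.01)          # mirrored components
  low <- p[p < 0.5]
  expect_equal(mean(low), 1 / 101, tolerance = 0.005)   # Beta(1,100) mean
  expect_equal(mean(sample_nonnull_p(100, 1e4, low_only = TRUE)),
               1 / 101, tolerance = 0.005)
  expect_error(sample_nonnull_p(0.5, 10))
})

test_that("independent scenario plants per-study and replicable non-nulls", {
  sim <- simulate_independent(n = 1000, m = 8, per_study_nonnull = 60,
                              replicable_genes = 10, extra_studies = 3,
                              x = 100, seed = 102)
  expect_true(all(colSums(sim$H) >= 60))
  # every replicable gene is non-null in at least extra_studies studies
  expect_true(all(rowSums(sim$H[1:10, ]) >= 3))
  # extra-study draws come from the low component only: at least 3 low
  # p-values per replicable gene
  expect_true(all(rowSums(sim$P$values[1:10, ] < qbeta(0.999, 1, 100)) >= 3))
  # determinism
  sim2 <- simulate_independent(n = 1000, m = 8, per_study_nonnull = 60,
                               replicable_genes = 10, extra_studies = 3,
                               x = 100, seed = 102)
  expect_identical(sim$P$values, sim2$P$values)
  expect_identical(sim$H, sim2$H)
})

test_that("null cells are uniform", {
  sim <- simulate_independent(n = 2000, m = 4, per_study_nonnull = 100,
                              replicable_genes = 0, extra_studies = 0,
                              x = 100, seed = 103)
  nulls <- sim$P$values[sim$H == 0]
  ks <- suppressWarnings(stats::ks.test(nulls, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("clustered scenario hits the marginal rate and block structure", {
  sim <- simulate_clustered(n = 5000, M = 4, cluster_size = 10, r = 0.8,
                            x = 100, seed = 104)
  # expected 6% non-nulls per study (300 of 5000), binomial error ~ 5 sd
  expect_true(all(abs(colSums(sim$H) - 300) < 5 * sqrt(5000 * 0.06 * 0.94)))
  phi <- suppressWarnings(stats::cor(sim$H))
  within <- phi[1:10, 1:10][upper.tri(diag(10))]
  across <- phi[1:10, 11:40]
  expect_gt(min(within), max(across))
  expect_gt(mean(within), 0.3)
  # r = 0: columns essentially uncorrelated
  sim0 <- simulate_clustered(n = 5000, M = 2, cluster_size = 4, r = 0,
                             x = 100, seed = 105)
  phi0 <- suppressWarnings(stats::cor(sim0$H))
  expect_lt(max(abs(phi0[upper.tri(phi0)])), 0.05)
  expect_error(simulate_clustered(r = 1), "correlation")
})

test_that("generative-model oracle fdr agrees with enumeration on a tiny case", {
  sim <- simulate_clustered(n = 300, M = 2, cluster_size = 3, r = 0.6,
                            x = 100, seed = 106)
  oracle <- oracle_fdr_clustered(sim, k = c(2, 4))
  expect_true(all(oracle >= 0 & oracle <= 1))
  # independent check: exchangeable per-cluster prior by direct quadrature +
  # brute force over the 64 joint configurations with the true densities
  tau <- qnorm(0.94)
  w <- seq(-8, 8, length.out = 4001); dw <- w[2] - w[1]
  pw <- pnorm((sqrt(0.6) * w - tau) / sqrt(0.4))
  wc <- vapply(0:3, function(c) sum(dnorm(w) * pw^c * (1 - pw)^(3 - c)) * dw,
               numeric(1))
  cfg6 <- screenrep:::all_configs(6)
  pr <- apply(cfg6, 1, function(h) {
    wc[sum(h[1:3]) + 1] * wc[sum(h[4:6]) + 1]
  })
  f1 <- function(p) 0.5 * dbeta(p, 1, 100) + 0.5 * dbeta(p, 100, 1)
  for (i in c(1, 17, 101)) {
    pv <- sim$P$values[i, ]
    lik <- apply(cfg6, 1, function(h) prod(ifelse(h == 1, f1(pv), 1)))
    w_post <- lik * pr / sum(lik * pr)
    for (kk in c(2, 4)) {
      expect_equal(oracle[i, paste0("fdr_k", kk)],
                   sum(w_post[rowSums(cfg6) < kk]),
                   tolerance = 1e-6, ignore_attr = TRUE)
    }
  }
})
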