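# Exact fdr_k under independence: trivial reductions, agreement with the
# enumeration oracle, and normalization/monotonicity properties.

test_that("single study, k = 1 reduces to the marginal local fdr", {
  set.seed(1)
  mdl <- abs_model(pi0 = 0.88, mu = 3)
  z <- matrix(abs(rnorm(30)) + rep(c(0, 3), 15), ncol = 1)
  Z <- study_matrix(z, scale = "zscore")
  res <- fdr_k_independent(Z, list(mdl), k = 1)
  expect_equal(unname(res$fdr[, 1]), local_fdr(mdl, z[, 1]), tolerance = 1e-12)
})

test_that("k = m + 1 gives fdr 1 for every gene", {
  inst <- random_instance(7, m = 5, n = 12)
  res <- fdr_k_independent(inst$Z, inst$models, k = 6)
  expect_equal(unname(res$fdr[, 1]), rep(1, 12))
})

test_that("dynamic program equals brute-force enumeration (property)", {
  worst <- 0
  for (seed in 1:60) {
    m <- 2 + (seed %% 7)  # m in 2..8
    inst <- random_instance(seed, m = m, n = 6)
    for (k in unique(c(1, 2, m, m + 1))) {
      res <- fdr_k_independent(inst$Z, inst$models, k = k)
      bf <- vapply(seq_len(inst$n), function(i) {
        brute_force_fdr_k(inst$Z$values[i, ], inst$models, k)
      }, numeric(1))
      worst <- max(worst, max(abs(unname(res$fdr[, 1]) - bf)))
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("posterior count distribution normalizes and fdr_k is monotone in k", {
  inst <- random_instance(99, m = 9, n = 25)
  counts <- screenrep:::posterior_counts_independent(inst$Z, inst$models)
  expect_true(all(abs(rowSums(counts) - 1) < 1e-9))
  res <- fdr_k_independent(inst$Z, inst$models, k = 1:10)
  expect_true(all(apply(res$fdr, 1, function(v) all(diff(v) >= -1e-12))))
})

test_that("brute force honors trivial priors and the m guard", {
  inst <- random_instance(5, m = 4, n = 3)
  # k = 1 with the independence prior: the all-null configuration only
  pi0 <- vapply(inst$models, function(mo) mo$pi0, numeric(1))
  z <- inst$Z$values[1, ]
  g0 <- vapply(1:4, function(j) {
    f0 <- screenrep:::model_f0(inst$models[[j]], z[j])
    f1 <- screenrep:::model_f1(inst$models[[j]], z[j])
    pi0[j] * f0 / (pi0[j] * f0 + (1 - pi0[j]) * f1)
  }, numeric(1))
  expect_equal(brute_force_fdr_k(z, inst$models, k = 1), prod(g0),
               tolerance = 1e-12)
  # uniform prior, k = m + 1: the whole posterior
  unif <- configuration_prior(screenrep:::all_configs(4), rep(1 / 16, 16))
  expect_equal(brute_force_fdr_k(z, inst$models, k = 5, prior = unif), 1)
  big <- random_instance(6, m = 3, n = 2)
  expect_error(brute_force_fdr_k(rep(0, 21), rep(big$models, 7), k = 1),
               "m > 20")
})

test_that("likelihood_sum_below_k matches enumeration and its closed forms", {
  inst <- random_instance(21, m = 6, n = 5)
  z <- inst$Z$values[3, ]
  F0 <- vapply(1:6, function(j) screenrep:::model_f0(inst$models[[j]], z[j]), numeric(1))
  F1 <- vapply(1:6, function(j) screenrep:::model_f1(inst$models[[j]], z[j]), numeric(1))
  H <- screenrep:::all_configs(6)
  lik <- apply(H, 1, function(h) prod(ifelse(h == 1, F1, F0)))
  for (k in c(1, 3, 7)) {
    expect_equal(likelihood_sum_below_k(z, inst$models, k),
                 sum(lik[rowSums(H) < k]), tolerance = 1e-12)
  }
  # k = 1: only the all-null configuration contributes
  expect_equal(likelihood_sum_below_k(z, inst$models, 1), prod(F0))
  # k = m + 1 factorizes
  expect_equal(likelihood_sum_below_k(z, inst$models, 7), prod(F0 + F1),
               tolerance = 1e-12)
})
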