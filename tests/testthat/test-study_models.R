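# Two-groups model fitting, local fdr, power and shrinkage.

test_that("pvals_to_zscores maps quantiles correctly and clips", {
  P <- study_matrix(matrix(c(0.5, 0.025, 1e-300, 0.9), 2, 2),
                    scale = "pvalue")
  Z <- pvals_to_zscores(P)
  expect_equal(Z$values[1, 1], 0)
  expect_equal(Z$values[2, 1], 1.959964, tolerance = 1e-6)
  # clipping keeps the most extreme p finite at qnorm(1 - 1e-15)
  expect_equal(Z$values[1, 2], qnorm(1 - 1e-15))
  expect_true(all(is.finite(Z$values)))
  # monotone decreasing in p
  p <- seq(0.01, 0.99, by = 0.01)
  Pm <- study_matrix(cbind(p, p), scale = "pvalue")
  expect_true(all(diff(pvals_to_zscores(Pm)$values[, 1]) < 0))
  expect_error(pvals_to_zscores(study_matrix(matrix(rnorm(4), 2), scale = "zscore")))
})

test_that("fit_normix recovers a known mixture and respects constraints", {
  maes <- vapply(1:20, function(r) {
    set.seed(100 + r)
    z <- c(rnorm(4500), rnorm(500, 3))
    fit <- fit_normix(z)
    expect_gte(fit$f0$s, 1)
    expect_gt(fit$f1$mu, 0)
    expect_true(all(diff(fit$details$loglik) > -1e-8))  # EM monotone
    abs(fit$pi0 - 0.9)
  }, numeric(1))
  expect_lt(maes[1], 0.05)      # single-replicate recovery
  expect_lt(mean(maes), 0.05)   # mean absolute error over 20 replicates
})

test_that("fit_normix handles pure-null and degenerate input", {
  set.seed(1)
  fit <- fit_normix(rnorm(3000))
  expect_gte(fit$pi0, 0.9)
  expect_error(fit_normix(rep(1, 500)), "degenerate")
  expect_error(fit_normix(rnorm(50)), "at least")
})

test_that("fitted densities integrate to one on their domain", {
  set.seed(2)
  fit <- fit_normix(c(rnorm(2000), rnorm(300, 3.5)))
  expect_equal(screenrep:::dens_integral(fit$f0), 1, tolerance = 1e-6)
  expect_equal(screenrep:::dens_integral(fit$f1), 1, tolerance = 1e-6)
})

test_that("fit_locfdr_style recovers null parameters and reports its branch", {
  set.seed(11)
  fit0 <- fit_locfdr_style(rnorm(5000))
  expect_true(fit0$details$branch %in% c("mle", "central_matching", "theoretical"))
  expect_lt(abs(fit0$details$null_mean), 0.1)
  expect_gte(fit0$pi0, 0.9)

  # shifted wide null plus a small non-null group keeps pi0 identifiably
  # below 1, so the empirical-null branches engage
  set.seed(12)
  z <- c(rnorm(4650, 0.5, 1.2), rnorm(350, 3.5))
  fit <- fit_locfdr_style(z)
  expect_true(fit$details$branch %in% c("mle", "central_matching"))
  expect_lt(abs(fit$details$null_mean - 0.5), 0.15)

  # fewer than 200 points must go straight to the theoretical null
  set.seed(13)
  small <- fit_locfdr_style(rnorm(150))
  expect_identical(small$details$branch, "theoretical")
  expect_identical(small$details$null_mean, 0)
})

test_that("local_fdr matches the density-ratio oracle and edge cases", {
  mdl <- signed_model(pi0 = 0.9, mu = 3)
  expect_equal(local_fdr(mdl, 3), 0.09089336, tolerance = 1e-6)
  expect_true(all(local_fdr(mdl, seq(-5, 5, 0.5)) >= 0))
  expect_true(all(local_fdr(mdl, seq(-5, 5, 0.5)) <= 1))
  # pi0 = 1: everything null
  mdl1 <- two_groups_model(1, screenrep:::dens_norm(), screenrep:::dens_norm(3, 1),
                           domain = "signed_z")
  expect_equal(local_fdr(mdl1, c(-2, 0, 5)), c(1, 1, 1))
  # f1 = 0 at z: posterior collapses to null
  mdl2 <- two_groups_model(0.5, screenrep:::dens_unif(), screenrep:::dens_grid(c(0, 1), c(2, 0)),
                           domain = "signed_z")
  expect_equal(local_fdr(mdl2, 1), 1)
})

test_that("local fdr is monotone in |z| for a monotone likelihood ratio", {
  mdl <- abs_model(pi0 = 0.85, mu = 3)
  z <- seq(0, 6, by = 0.1)
  expect_true(all(diff(local_fdr(mdl, z)) <= 1e-12))
})

test_that("estimate_power matches Monte Carlo and limits", {
  # f1 == f0: tdr is constant at 1 - pi0
  same <- two_groups_model(0.9, screenrep:::dens_halfnorm(1),
                           screenrep:::dens_halfnorm(1), domain = "absolute_z")
  expect_equal(estimate_power(same), 0.1, tolerance = 1e-6)
  # perfect separation
  far <- abs_model(pi0 = 0.9, mu = 20)
  expect_gte(estimate_power(far), 0.99)
  # pi0 = 1 convention
  none <- two_groups_model(1, screenrep:::dens_halfnorm(1),
                           screenrep:::dens_folded(3), domain = "absolute_z")
  expect_equal(estimate_power(none), 0)
  # Monte Carlo oracle: draws from f1, average tdr
  mdl <- abs_model(pi0 = 0.85, mu = 2.5)
  set.seed(42)
  draws <- abs(rnorm(1e6, 2.5))
  mc <- mean(1 - local_fdr(mdl, draws))
  expect_equal(estimate_power(mdl), mc, tolerance = 0.01)
})

test_that("shrink_f1 scales the non-null density pointwise", {
  mdl <- abs_model(pi0 = 0.8, mu = 3)
  z <- seq(0, 5, 0.25)
  m1 <- mdl; m1$power <- 1
  expect_equal(screenrep:::model_f1(shrink_f1(m1), z),
               screenrep:::model_f1(mdl, z))
  m0 <- mdl; m0$power <- 0
  s0 <- shrink_f1(m0)
  expect_equal(screenrep:::model_f1(s0, z), rep(0, length(z)))
  expect_equal(local_fdr(s0, z), rep(1, length(z)))
  mh <- mdl; mh$power <- 0.5
  expect_equal(screenrep:::model_f1(shrink_f1(mh), z),
               0.5 * screenrep:::model_f1(mdl, z))
})

test_that("two-groups models round-trip through the text serialization", {
  set.seed(3)
  fit <- shrink_f1(fit_normix(c(rnorm(2000), rnorm(300, 3))))
  path <- tempfile(fileext = ".tsv")
  write_two_groups_model(fit, path)
  back <- read_two_groups_model(path)
  z <- seq(0, 6, 0.2)
  expect_equal(back$pi0, fit$pi0)
  expect_equal(local_fdr(back, z), local_fdr(fit, z))
})
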