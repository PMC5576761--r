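# Per-cluster count posteriors and the cross-cluster merge DP.

test_that("singleton cluster reduces to the two-configuration posterior", {
  inst <- random_instance(61, m = 3, n = 40)
  post <- cluster_count_posteriors(inst$Z, inst$models, cluster = 2L)
  expect_equal(dim(post$table), c(40L, 2L))
  expect_true(all(abs(rowSums(post$table) - 1) < 1e-9))
  # with a supplied prior the null column is the exact marginal posterior
  pi_null <- 0.8
  prior <- configuration_prior(matrix(c(0, 1), ncol = 1), c(pi_null, 1 - pi_null))
  post2 <- cluster_count_posteriors(inst$Z, inst$models, cluster = 2L,
                                    prior = prior)
  z2 <- inst$Z$values[, 2]
  f0 <- screenrep:::model_f0(inst$models[[2]], z2)
  f1 <- screenrep:::model_f1(inst$models[[2]], z2)
  expect_equal(unname(post2$table[, 1]),
               unname(pi_null * f0 / (pi_null * f0 + (1 - pi_null) * f1)),
               tolerance = 1e-12)
})

test_that("cluster count posteriors match brute-force counting (property)", {
  for (seed in 62:71) {
    m <- 3 + (seed %% 3)
    inst <- random_instance(seed, m = m, n = 8)
    prior <- random_full_prior(seed, m)
    post <- cluster_count_posteriors(inst$Z, inst$models,
                                     cluster = seq_len(m), prior = prior)
    bf <- t(vapply(seq_len(inst$n), function(i) {
      brute_force_count_posterior(inst$Z$values[i, ], inst$models, prior)
    }, numeric(m + 1)))
    expect_lt(max(abs(unname(post$table) - bf)), 1e-8)
  }
})

test_that("merging singleton clusters equals the independence DP", {
  inst <- random_instance(72, m = 6, n = 30)
  pi0 <- vapply(inst$models, function(mo) mo$pi0, numeric(1))
  posts <- lapply(1:6, function(j) {
    prior <- configuration_prior(matrix(c(0, 1), ncol = 1),
                                 c(pi0[j], 1 - pi0[j]))
    cluster_count_posteriors(inst$Z, inst$models, cluster = j, prior = prior)
  })
  for (k in c(1, 2, 4, 7)) {
    merged <- merge_clusters(posts, k = k)
    ind <- fdr_k_independent(inst$Z, inst$models, k = k)
    expect_equal(unname(merged$fdr), unname(ind$fdr), tolerance = 1e-10)
  }
})

test_that("merge of two clusters equals brute force under the product prior", {
  for (seed in 73:78) {
    inst <- random_instance(seed, m = 6, n = 6)
    prA <- random_full_prior(seed, 3)
    prB <- random_full_prior(seed + 1000, 3)
    postA <- cluster_count_posteriors(inst$Z, inst$models, cluster = 1:3,
                                      prior = prA)
    postB <- cluster_count_posteriors(inst$Z, inst$models, cluster = 4:6,
                                      prior = prB)
    # product prior over the 64 joint configurations
    cfg6 <- screenrep:::all_configs(6)
    pjoint <- screenrep:::prior_lookup(prA, cfg6[, 1:3]) *
      screenrep:::prior_lookup(prB, cfg6[, 4:6])
    joint <- configuration_prior(cfg6, pjoint)
    for (k in c(2, 4)) {
      merged <- merge_clusters(list(postA, postB), k = k)
      bf <- vapply(seq_len(inst$n), function(i) {
        brute_force_fdr_k(inst$Z$values[i, ], inst$models, k, prior = joint)
      }, numeric(1))
      expect_lt(max(abs(unname(merged$fdr[, 1]) - bf)), 1e-10)
    }
  }
})

test_that("merged fdr_k is monotone in k and a single cluster passes through", {
  inst <- random_instance(79, m = 5, n = 20)
  prior <- random_full_prior(79, 5)
  post <- cluster_count_posteriors(inst$Z, inst$models, cluster = 1:5,
                                   prior = prior)
  merged <- merge_clusters(list(post), k = 1:6)
  expect_true(all(apply(merged$fdr, 1, function(v) all(diff(v) >= -1e-12))))
  expect_equal(unname(merged$fdr[, 3]), unname(rowSums(post$table[, 1:3])),
               tolerance = 1e-12)
})

test_that("screen pipeline is deterministic under a fixed master seed", {
  sim <- simulate_clustered(n = 600, M = 2, cluster_size = 3, r = 0.8,
                            x = 1000, seed = 80)
  r1 <- screen(sim$P, k = 2:3, bootstrap = 5, seed = 11)
  r2 <- screen(sim$P, k = 2:3, bootstrap = 5, seed = 11)
  expect_identical(r1$fdr, r2$fdr)
  expect_identical(attr(r1, "clusters"), attr(r2, "clusters"))
})

test_that("screen on two independent studies matches brute force", {
  set.seed(81)
  n <- 2000
  h <- matrix(rbinom(n * 2, 1, 0.1), n, 2)
  z <- matrix(rnorm(n * 2), n, 2); z[h == 1] <- rnorm(sum(h), 3.5)
  Z <- study_matrix(abs(z), scale = "zscore")
  res <- screen(Z, k = 2, bootstrap = 10, seed = 81)
  # oracle: brute force under the per-cluster EM priors actually used
  posts <- attr(res, "posteriors")
  expect_true(all(lengths(attr(res, "clusters")) == 1))
  prior_prod <- configuration_prior(
    screenrep:::all_configs(2),
    screenrep:::prior_lookup(posts[[1]]$prior, matrix(c(0, 1), 2, 1)) [c(1, 1, 2, 2)] *
      screenrep:::prior_lookup(posts[[2]]$prior, matrix(c(0, 1), 2, 1))[c(1, 2, 1, 2)])
  models <- attr(res, "models")
  bf <- vapply(1:20, function(i) {
    brute_force_fdr_k(Z$values[i, ], models, 2, prior = prior_prod)
  }, numeric(1))
  expect_equal(unname(res$fdr[1:20, 1]), bf, tolerance = 1e-8)
})
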