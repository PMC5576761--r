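# Shared fixtures: quick model constructors and random instances for the
# enumeration-oracle tests. All randomness is seeded by the caller.

# absolute-scale two-groups model with known parameters
abs_model <- function(pi0 = 0.9, mu = 3, s = 1, shrink = 1) {
  m <- two_groups_model(pi0, screenrep:::dens_halfnorm(s),
                        screenrep:::dens_folded(mu), domain = "absolute_z",
                        shrink = shrink)
  m
}

# signed-scale model with normal components (for closed-form fdr checks)
signed_model <- function(pi0 = 0.9, mu = 3) {
  two_groups_model(pi0, screenrep:::dens_norm(0, 1),
                   screenrep:::dens_norm(mu, 1), domain = "signed_z")
}

# a random m-study instance: models with varying pi0/mu and an n x m z matrix
# containing a mix of null and non-null draws
random_instance <- function(seed, m, n = 10) {
  set.seed(seed)
  models <- lapply(seq_len(m), function(j) {
    abs_model(pi0 = runif(1, 0.6, 0.95), mu = runif(1, 2, 4),
              shrink = runif(1, 0.5, 1))
  })
  z <- matrix(abs(rnorm(n * m) + 3 * rbinom(n * m, 1, 0.2)), n, m)
  list(models = models,
       Z = study_matrix(z, scale = "zscore"),
       m = m, n = n)
}

# a random prior over the full configuration space of m studies
random_full_prior <- function(seed, m, concentration = 0.1) {
  set.seed(seed)
  p <- rgamma(2^m, concentration) + 1e-12
  configuration_prior(screenrep:::all_configs(m), p / sum(p))
}

# simulated two-study data with a known 4-configuration prior
pair_config_data <- function(seed, n = 5000, probs = c(0.85, 0.05, 0.05, 0.05),
                             mu = 3) {
  set.seed(seed)
  cfgs <- screenrep:::all_configs(2)
  hidx <- sample.int(4, n, replace = TRUE, prob = probs)
  z <- matrix(rnorm(n * 2), n, 2)
  for (j in 1:2) {
    nn <- cfgs[hidx, j] == 1
    z[nn, j] <- rnorm(sum(nn), mu)
  }
  list(Z = study_matrix(abs(z), scale = "zscore"),
       models = list(abs_model(mu = mu), abs_model(mu = mu)),
       truth = probs, configs = cfgs)
}
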