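# Exact fdr_k under study independence: an O(nmk) dynamic program over the
# number of non-null realizations, plus brute-force enumeration oracles.

# Count dynamic program. A and B are n x m matrices of per-study weights for
# the null (h_j = 0) and non-null (h_j = 1) state. Returns an n x (cmax + 1)
# matrix T with T[, c + 1] = sum over configurations h of the first m studies
# with |h| = c of prod_j A[,j]^(1-h_j) B[,j]^h_j. Counts above cmax are
# dropped (not accumulated).
count_dp <- function(A, B, cmax = ncol(A)) {
  n <- nrow(A); m <- ncol(A)
  cmax <- min(cmax, m)
  T <- matrix(0, n, cmax + 1L)
  T[, 1L] <- 1
  for (j in seq_len(m)) {
    if (cmax >= 1L) {
      for (cc in seq(cmax + 1L, 2L)) {
        T[, cc] <- A[, j] * T[, cc] + B[, j] * T[, cc - 1L]
      }
    }
    T[, 1L] <- A[, j] * T[, 1L]
  }
  T
}

# all 2^m configurations as an (2^m) x m 0/1 matrix, in lexicographic order
# with the first study as the most significant bit
all_configs <- function(m) {
  stopifnot(m <= 20L)
  idx <- 0:(2^m - 1)
  sapply(seq_len(m), function(j) bitwAnd(idx %/% 2^(m - j), 1L))
}

#' Exact fdr_k under study independence (dynamic program)
#'
#' For each gene, computes the posterior probability that it is non-null in
#' fewer than k studies, assuming the studies are independent in the
#' parameter space so that the configuration prior factorizes into the
#' per-study null priors pi0_j. Per-study posterior non-null probabilities
#' (the local tdr values) are convolved by a count dynamic program in
#' O(nmk) time.
#'
#' @param x a \code{study_matrix} (p-values are converted to z-scores).
#' @param models list of fitted \code{two_groups_model}, one per study.
#' @param k integer vector of replication levels, each in 1..m+1
#'   (k = m+1 gives fdr = 1: no configuration can reach m+1 non-nulls).
#' @param threshold selection threshold on the fdr (default 0.2).
#' @return an \code{fdr_result}.
#' @export
fdr_k_independent <- function(x, models, k, threshold = 0.2) {
  comp <- lik_components(x, models)
  m <- ncol(comp$F0)
  k <- as.integer(k)
  stopifnot(all(k >= 1L), all(k <= m + 1L))
  G0 <- sweep(comp$F0, 2, comp$pi0, "*")
  G1 <- sweep(comp$F1, 2, 1 - comp$pi0, "*")
  f <- G0 + G1
  if (any(f == 0)) {
    warning("per-study marginal density is zero for some cells; treating them as null")
    bad <- f == 0
    G0[bad] <- 1; f[bad] <- 1
  }
  counts <- count_dp(G0 / f, G1 / f, cmax = min(max(k) - 1L, m))
  fdr <- sapply(k, function(kk) {
    if (kk == m + 1L) rep(1, nrow(counts))
    else rowSums(counts[, seq_len(kk), drop = FALSE])
  })
  fdr_result(comp$gene_ids, k, pmin(fdr, 1), threshold = threshold)
}

# posterior count distribution (counts 0..m) under independence; used by
# tests and by the merge driver when every cluster is a singleton
posterior_counts_independent <- function(x, models) {
  comp <- lik_components(x, models)
  G0 <- sweep(comp$F0, 2, comp$pi0, "*")
  G1 <- sweep(comp$F1, 2, 1 - comp$pi0, "*")
  f <- pmax(G0 + G1, 1e-300)
  count_dp(G0 / f, G1 / f)
}

#' Brute-force fdr_k by enumeration over all configurations
#'
#' Enumerates the 2^m binary configurations, computes the conditional
#' likelihood P(Z_row | h) as the product of per-study f0/f1 values, weights
#' each configuration by its prior, and returns the exact posterior mass of
#' configurations with fewer than k ones. Serves as the independent oracle
#' for the dynamic programs; refuses m > 20.
#'
#' @param z_row numeric vector of m statistics for one gene, on the z scale.
#' @param models list of m fitted \code{two_groups_model}.
#' @param k replication level in 1..m+1.
#' @param prior a \code{\link{configuration_prior}} over full-length
#'   configurations, or \code{NULL} for the independence product prior built
#'   from the models' pi0 values.
#' @return the exact fdr_k value.
#' @export
brute_force_fdr_k <- function(z_row, models, k, prior = NULL) {
  post <- brute_force_count_posterior(z_row, models, prior)
  m <- length(z_row)
  if (k == m + 1L) return(1)
  sum(post[seq_len(k)])
}

#' Brute-force posterior distribution of the non-null count
#'
#' @inheritParams brute_force_fdr_k
#' @return numeric vector of length m+1; element c+1 is the exact posterior
#'   probability that the gene has exactly c non-null realizations.
#' @export
brute_force_count_posterior <- function(z_row, models, prior = NULL) {
  m <- length(z_row)
  if (m > 20L) stop("brute force enumeration refuses m > 20")
  H <- all_configs(m)
  f0 <- vapply(seq_len(m), function(j) model_f0(models[[j]], z_row[j]), numeric(1))
  f1 <- vapply(seq_len(m), function(j) model_f1(models[[j]], z_row[j]), numeric(1))
  lik <- apply(H, 1, function(h) prod(ifelse(h == 1, f1, f0)))
  if (is.null(prior)) {
    pi0 <- vapply(models, function(mo) mo$pi0, numeric(1))
    pr <- apply(H, 1, function(h) prod(ifelse(h == 1, 1 - pi0, pi0)))
  } else {
    pr <- prior_lookup(prior, H)
  }
  w <- lik * pr
  tot <- sum(w)
  if (tot == 0) stop("zero marginal likelihood in brute force oracle")
  post <- numeric(m + 1L)
  cnt <- rowSums(H)
  for (c in 0:m) post[c + 1L] <- sum(w[cnt == c]) / tot
  post
}

#' Dynamic-programming sum of likelihoods over low-count configurations
#'
#' Computes the prior-free quantity sum over all h with |h| < k of
#' prod_j f0_j or f1_j at the gene's statistics; this is the term multiplied
#' by epsilon inside the fdr upper bound. k = 1 admits only the all-null
#' configuration (the product of the f0 values); k = m+1 factorizes into
#' prod_j (f0_j + f1_j).
#'
#' @param z_row numeric vector of m statistics on the z scale (or an n x m
#'   matrix, in which case a vector of sums is returned).
#' @param models list of fitted models.
#' @param k replication level in 1..m+1.
#' @return nonnegative scalar (or vector for matrix input).
#' @export
likelihood_sum_below_k <- function(z_row, models, k) {
  Zm <- if (is.matrix(z_row)) z_row else matrix(z_row, nrow = 1)
  m <- ncol(Zm)
  stopifnot(k >= 1L, k <= m + 1L)
  F0 <- sapply(seq_len(m), function(j) model_f0(models[[j]], Zm[, j]))
  F1 <- sapply(seq_len(m), function(j) model_f1(models[[j]], Zm[, j]))
  if (!is.matrix(F0)) { F0 <- matrix(F0, nrow = 1); F1 <- matrix(F1, nrow = 1) }
  T <- count_dp(F0, F1, cmax = min(k - 1L, m))
  out <- rowSums(T[, seq_len(min(k, m + 1L)), drop = FALSE])
  if (is.matrix(z_row)) out else out[[1]]
}
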