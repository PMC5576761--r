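# Prior estimation over binary study-configuration vectors: unrestricted EM
# over an explicit support, the restricted EM that caps the number of
# configurations kept in memory (tracking retained mass xi and exclusion
# bound epsilon), and the resulting fdr_k upper bound.

#' Construct a prior over binary study configurations
#'
#' @param configs 0/1 matrix, one configuration per row (all the same length).
#' @param probs probabilities pi(h), one per retained configuration; their sum
#'   is the retained mass and may be below 1 after truncation.
#' @param retained_mass total prior mass of the retained set (xi).
#' @param exclusion_bound upper bound epsilon on the prior probability of any
#'   excluded configuration.
#' @param capacity the memory cap n_H the prior was built under.
#' @return an object of class \code{configuration_prior}.
#' @export
configuration_prior <- function(configs, probs, retained_mass = sum(probs),
                                exclusion_bound = 0, capacity = nrow(configs)) {
  configs <- as.matrix(configs)
  stopifnot(nrow(configs) == length(probs), all(configs %in% c(0, 1)),
            all(probs >= -1e-12), sum(probs) <= 1 + 1e-9,
            exclusion_bound >= 0)
  structure(list(configs = configs, probs = pmax(probs, 0),
                 retained_mass = retained_mass,
                 exclusion_bound = exclusion_bound, capacity = capacity),
            class = "configuration_prior")
}

#' @export
print.configuration_prior <- function(x, ...) {
  cat(sprintf(
    "configuration_prior: %d configs of length %d, xi = %.4f, epsilon = %.3g\n",
    nrow(x$configs), ncol(x$configs), x$retained_mass, x$exclusion_bound))
  invisible(x)
}

config_keys <- function(configs) apply(configs, 1, paste, collapse = "")

# probabilities for arbitrary configurations (0 for excluded ones)
prior_lookup <- function(prior, configs) {
  keys <- config_keys(as.matrix(configs))
  idx <- match(keys, config_keys(prior$configs))
  out <- prior$probs[idx]
  out[is.na(out)] <- 0
  out
}

# log-likelihood matrix genes x configs: log P(Z_row | h) = sum_j log f_{h_j}
# built from precomputed per-study F0/F1 matrices (columns already subset)
config_loglik <- function(F0, F1, configs) {
  logF0 <- log(pmax(F0, 1e-300))
  logF1 <- log(pmax(F1, 1e-300))
  logF0 %*% t(1 - configs) + logF1 %*% t(configs)
}

# EM core on a fixed likelihood matrix L (rows scaled arbitrarily; row
# scaling cancels in the E-step and shifts the log-likelihood by a constant).
# Returns probs, loglik trace (up to the row-scaling constant), convergence.
em_core <- function(L, start = NULL, tol = 1e-6, max_iter = 2000L) {
  n <- nrow(L); s <- ncol(L)
  pi <- if (is.null(start)) rep(1 / s, s) else start / sum(start)
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    u <- as.vector(L %*% pi)
    u <- pmax(u, 1e-300)
    ll <- sum(log(u))
    trace <- c(trace, ll)
    pi_new <- pi * as.vector(crossprod(L, 1 / u)) / n
    pi_new <- pmax(pi_new, 0)
    pi_new <- pi_new / sum(pi_new)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      pi <- pi_new
      break
    }
    pi <- pi_new
    ll_old <- ll
  }
  list(probs = pi, loglik = trace, converged = converged)
}

#' Unrestricted EM over an explicit configuration support
#'
#' Estimates the prior pi(h) over a given set of binary configurations by EM
#' on the full data: the E-step computes posterior configuration
#' probabilities per gene, the M-step averages them. The observed-data
#' log-likelihood is non-decreasing across iterations, and any configuration
#' whose probability reaches zero stays at zero, so constraining the support
#' simply means starting from it. The start is deterministic (uniform over
#' the support unless \code{start} is given).
#'
#' @param x a \code{study_matrix} (columns must match the configuration
#'   length), or \code{NULL} if \code{components} is supplied.
#' @param models list of fitted models, one per study.
#' @param support 0/1 matrix of configurations, one per row.
#' @param start optional starting probabilities over the support.
#' @param tol absolute tolerance on the log-likelihood change.
#' @param max_iter maximum EM iterations.
#' @param components precomputed output of the internal likelihood builder;
#'   used by drivers to avoid recomputing densities.
#' @return a \code{configuration_prior} with \code{retained_mass = 1},
#'   \code{exclusion_bound = 0}; the fit trace is in \code{attr(, "fit")}.
#' @export
em_unrestricted <- function(x, models, support, start = NULL,
                            tol = 1e-6, max_iter = 2000L, components = NULL) {
  support <- as.matrix(support)
  comp <- if (is.null(components)) lik_components(x, models) else components
  stopifnot(ncol(support) == ncol(comp$F0))
  logL <- config_loglik(comp$F0, comp$F1, support)
  shift <- apply(logL, 1, max)
  keep <- is.finite(shift)
  if (!all(keep)) {
    warning(sum(!keep), " gene(s) with zero likelihood under every configuration dropped")
    logL <- logL[keep, , drop = FALSE]
    shift <- shift[keep]
  }
  L <- exp(logL - shift)
  fit <- em_core(L, start = start, tol = tol, max_iter = max_iter)
  out <- configuration_prior(support, fit$probs, retained_mass = 1,
                             exclusion_bound = 0,
                             capacity = nrow(support))
  attr(out, "fit") <- list(loglik = fit$loglik + sum(shift),
                           converged = fit$converged)
  out
}

#' Restricted EM over at most n_H configurations (repfdr-UB prior)
#'
#' Builds the configuration prior one study at a time under a memory cap of
#' n_H configurations. Starting from the full configuration space of the
#' first log2(n_H) - 1 studies, each round extends every retained
#' configuration by 0 and 1, re-runs the EM on the extended support (warm
#' started by splitting each previous probability equally between its two
#' extensions), rescales the result by the previous retained mass xi, keeps
#' the top n_H/2 configurations (ties broken toward lexicographically
#' smallest bit-vectors), and updates xi (retained mass) and epsilon (the
#' largest probability ever excluded). The final round keeps up to n_H
#' configurations since no further extension follows. When 2^m <= n_H the
#' full space fits in memory and the unrestricted EM is returned directly
#' (xi = 1, epsilon = 0).
#'
#' @param x a \code{study_matrix}.
#' @param models list of fitted models, one per study.
#' @param n_H memory cap; a power of two, at least 4 (rounded down with a
#'   warning otherwise).
#' @param tol,max_iter EM controls per round.
#' @return a \code{configuration_prior} over full-length configurations with
#'   its \code{retained_mass} and \code{exclusion_bound} filled in.
#' @export
em_restricted <- function(x, models, n_H = 1024L, tol = 1e-6, max_iter = 2000L) {
  comp <- lik_components(x, models)
  m <- ncol(comp$F0)
  if (n_H < 4) stop("n_H must be at least 4")
  if (log2(n_H) %% 1 != 0) {
    n_H <- 2^floor(log2(n_H))
    warning("n_H is not a power of two; rounded down to ", n_H)
  }
  if (2^m <= n_H) {
    out <- em_unrestricted(NULL, models, all_configs(m), components = comp,
                           tol = tol, max_iter = max_iter)
    out$capacity <- n_H
    return(out)
  }

  l0 <- as.integer(log2(n_H)) - 1L
  sub <- function(l) list(F0 = comp$F0[, seq_len(l), drop = FALSE],
                          F1 = comp$F1[, seq_len(l), drop = FALSE])
  H <- all_configs(l0)
  fit0 <- em_unrestricted(NULL, models[seq_len(l0)], H, components = sub(l0),
                          tol = tol, max_iter = max_iter)
  probs <- fit0$probs
  xi <- 1
  eps <- 0
  for (l in seq(l0 + 1L, m)) {
    ext <- rbind(cbind(H, 0L), cbind(H, 1L))
    start <- rep(probs, 2) / 2
    start <- pmax(start, 1e-12)  # keep every extension reachable by the EM
    fit <- em_unrestricted(NULL, models[seq_len(l)], ext, components = sub(l),
                           start = start, tol = tol, max_iter = max_iter)
    p <- xi * fit$probs                           # update (1): rescale by xi
    n_keep <- if (l < m) n_H %/% 2L else min(length(p), n_H)
    if (length(p) > n_keep) {
      ord <- order(-p, config_keys(ext))          # update (2): top n_H/2,
      keep_idx <- sort(ord[seq_len(n_keep)])      # lexicographic tie-break
      drop_idx <- ord[-seq_len(n_keep)]
      eps <- max(eps, max(p[drop_idx]))           # update (4)
      H <- ext[keep_idx, , drop = FALSE]
      probs <- p[keep_idx]
    } else {
      H <- ext
      probs <- p
    }
    xi <- sum(probs)                              # update (3)
  }
  configuration_prior(H, probs, retained_mass = xi, exclusion_bound = eps,
                      capacity = n_H)
}

#' Upper bound on fdr_k from a truncated configuration prior
#'
#' Given the prior probabilities of a retained configuration set H' and an
#' upper bound epsilon on the probability of every excluded configuration,
#' returns
#' \deqn{\frac{\sum_{|h|<k, h \in H'} P(Z|h)(\pi(h)-\epsilon)
#'       + \epsilon \sum_{|h|<k} P(Z|h)}{\sum_{h \in H'} P(Z|h)\pi(h)},}
#' capped at 1. The epsilon term over all low-count configurations is
#' computed by \code{\link{likelihood_sum_below_k}} in O(mk), giving an
#' O(m(n_H + k)) per-gene cost. With H' the full space and epsilon = 0 the
#' bound equals the exact fdr_k.
#'
#' @param z_row numeric vector of m z-scale statistics for one gene, or an
#'   n x m matrix for many genes.
#' @param models list of fitted models.
#' @param prior a \code{configuration_prior} over full-length configurations.
#' @param k replication level in 1..m+1.
#' @return upper bound(s) in [0,1]; a zero denominator yields 1 with a
#'   warning.
#' @export
fdr_k_upper_bound <- function(z_row, models, prior, k) {
  Zm <- if (is.matrix(z_row)) z_row else matrix(z_row, nrow = 1)
  m <- ncol(Zm)
  stopifnot(ncol(prior$configs) == m, k >= 1L, k <= m + 1L)
  F0 <- sapply(seq_len(m), function(j) model_f0(models[[j]], Zm[, j]))
  F1 <- sapply(seq_len(m), function(j) model_f1(models[[j]], Zm[, j]))
  if (!is.matrix(F0)) { F0 <- matrix(F0, nrow = 1); F1 <- matrix(F1, nrow = 1) }
  logL <- config_loglik(F0, F1, prior$configs)
  L <- exp(logL)  # raw likelihoods; magnitudes are moderate for m <= ~50
  eps <- prior$exclusion_bound
  low <- rowSums(prior$configs) < k
  num1 <- as.vector(L[, low, drop = FALSE] %*% (prior$probs[low] - eps))
  sall <- likelihood_sum_below_k(Zm, models, k)
  denom <- as.vector(L %*% prior$probs)
  out <- rep(1, nrow(Zm))
  ok <- denom > 0
  if (!all(ok)) warning("zero denominator in fdr upper bound; returning 1")
  out[ok] <- pmin((num1[ok] + eps * sall[ok]) / denom[ok], 1)
  out <- pmax(out, 0)
  if (is.matrix(z_row)) out else out[[1]]
}

#' Replicability upper bounds for all genes via the restricted EM
#'
#' The repfdr-UB driver: estimates a single configuration prior over all m
#' studies with \code{\link{em_restricted}}, then computes the fdr_k upper
#' bound for every gene and each requested k.
#'
#' @param x a \code{study_matrix}.
#' @param models list of fitted models (fitted from \code{x} if omitted).
#' @param k integer vector of replication levels.
#' @param n_H configuration memory cap.
#' @param threshold selection threshold on the bound.
#' @return an \code{fdr_result} with \code{is_bound = TRUE}; the estimated
#'   prior is attached as \code{attr(, "prior")}.
#' @export
repfdr_ub <- function(x, models = NULL, k = 2L, n_H = 1024L, threshold = 0.2) {
  if (is.null(models)) models <- fit_study_models(x)
  Z <- as_zscores(x)
  prior <- em_restricted(x, models, n_H = n_H)
  fdr <- sapply(as.integer(k), function(kk) {
    fdr_k_upper_bound(Z$values, models, prior, kk)
  })
  out <- fdr_result(rownames(Z$values), k, fdr, threshold = threshold,
                    is_bound = TRUE)
  attr(out, "prior") <- prior
  out
}
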