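# Study-dependence estimation in configuration space: two-study EM for the
# shared non-null probability, the phi-coefficient correlation, bootstrap
# averaging, and community detection on the thresholded network.

# four two-study configurations in lexicographic order: 00, 01, 10, 11
PAIR_CONFIGS <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), ncol = 2, byrow = TRUE)

# likelihood columns for the pair EM, precomputed once per study pair.
# The clustering stage deliberately uses the UNSHRUNKEN f1: the marginals
# a_i = 1 - pi0 come from the (unshrunken) two-groups fit, and mixing a
# power-shrunken likelihood into the pair EM biases a_ij below a_i a_j,
# turning independent study pairs into spurious negative correlations.
pair_lik <- function(z_i, z_j, model_i, model_j) {
  f0i <- model_f0(model_i, z_i)
  f1i <- dens_eval(model_i$f1, model_domain_z(model_i, z_i))
  f0j <- model_f0(model_j, z_j)
  f1j <- dens_eval(model_j$f1, model_domain_z(model_j, z_j))
  cbind(f0i * f0j, f0i * f1j, f1i * f0j, f1i * f1j)
}

#' Shared non-null probability of two studies via the pair EM
#'
#' Runs the unrestricted EM over the four configurations of a study pair and
#' returns the estimated prior probability that a gene is non-null in both,
#' a_ij = P(h_i = 1 and h_j = 1). If the EM degenerates the independence
#' product a_i * a_j is returned with a warning.
#'
#' @param z_i,z_j numeric vectors of z-scale statistics for the two studies.
#' @param model_i,model_j their fitted \code{two_groups_model}s.
#' @param tol,max_iter EM controls.
#' @return the estimated joint non-null probability.
#' @export
pairwise_joint_prior <- function(z_i, z_j, model_i, model_j,
                                 tol = 1e-6, max_iter = 500L) {
  L <- pair_lik(z_i, z_j, model_i, model_j)
  a_ij <- pair_em_joint(L, tol, max_iter)
  if (is.na(a_ij)) {
    warning("degenerate pair EM; falling back to the independence product")
    a_ij <- (1 - model_i$pi0) * (1 - model_j$pi0)
  }
  a_ij
}

pair_em_joint <- function(L, tol = 1e-6, max_iter = 500L, scaled = FALSE) {
  if (!scaled) L <- pair_scale(L)
  if (nrow(L) == 0) return(NA_real_)
  fit <- em_core(L, tol = tol, max_iter = max_iter)
  if (anyNA(fit$probs)) NA_real_ else fit$probs[4]
}

# drop zero-likelihood genes and scale rows to a max of 1 (scaling cancels in
# the E-step; done once per pair so bootstrap resamples skip it)
pair_scale <- function(L) {
  L <- L[rowSums(L) > 0, , drop = FALSE]
  L / pmax(L[, 1], L[, 2], L[, 3], L[, 4])
}

#' Phi-coefficient correlation between two studies' non-null indicators
#'
#' \code{r_ij = (a_ij - a_i a_j) / sqrt(a_i (1 - a_i) a_j (1 - a_j))},
#' clipped to [-1, 1]. Marginal probabilities at 0 or 1 make the coefficient
#' undefined; 0 is returned with a warning.
#'
#' @param a_i,a_j marginal non-null probabilities of the two studies.
#' @param a_ij their shared non-null probability.
#' @return the correlation in [-1, 1].
#' @export
study_correlation <- function(a_i, a_j, a_ij) {
  if (a_i <= 0 || a_i >= 1 || a_j <= 0 || a_j >= 1) {
    warning("marginal non-null probability at 0 or 1; correlation undefined, returning 0")
    return(0)
  }
  r <- (a_ij - a_i * a_j) / sqrt(a_i * (1 - a_i) * a_j * (1 - a_j))
  min(max(r, -1), 1)
}

#' Bootstrap-averaged study correlation
#'
#' Re-estimates a_ij on B bootstrap samples of floor(n/2) genes drawn with
#' replacement, converts each to a phi coefficient using the marginal
#' non-null probabilities from the fitted models (a_i = 1 - pi0_i), and
#' returns the mean. \code{resample = FALSE} is a test hook that uses all
#' genes once per run.
#'
#' @inheritParams pairwise_joint_prior
#' @param B number of bootstrap runs (default 100).
#' @param seed RNG seed for the resampling.
#' @param resample draw bootstrap samples (default) or use the full data.
#' @return the mean correlation over the B runs.
#' @export
bootstrap_correlation <- function(z_i, z_j, model_i, model_j, B = 100L,
                                  seed = NULL, resample = TRUE) {
  stopifnot(B >= 1L)
  if (!is.null(seed)) set.seed(seed)
  a_i <- 1 - model_i$pi0
  a_j <- 1 - model_j$pi0
  L <- pair_scale(pair_lik(z_i, z_j, model_i, model_j))
  n <- nrow(L)
  half <- max(2L, floor(n / 2))
  # full-data fit once; bootstrap replicates warm-start from it, which cuts
  # the per-replicate EM to a handful of iterations (the bagged mean then
  # hugs the full-data estimate, which is also its target)
  fit0 <- em_core(L, tol = 1e-5, max_iter = 500L)
  start <- pmax(fit0$probs, 1e-8)
  rs <- vapply(seq_len(B), function(b) {
    Lb <- if (resample) L[sample.int(n, half, replace = TRUE), , drop = FALSE] else L
    fit <- em_core(Lb, start = start, tol = 1e-4, max_iter = 30L)
    a_ij <- if (anyNA(fit$probs)) NA_real_ else fit$probs[4]
    if (is.na(a_ij)) a_ij <- a_i * a_j
    study_correlation(a_i, a_j, a_ij)
  }, numeric(1))
  mean(rs)
}

#' Estimate the full study-correlation structure
#'
#' Computes, for every study pair, the bootstrap-averaged configuration-space
#' correlation. Per-pair seeds are derived deterministically from the master
#' seed so individual pairs are reproducible in isolation.
#'
#' @param x a \code{study_matrix}.
#' @param models list of fitted models, one per study.
#' @param B bootstrap runs per pair.
#' @param seed master seed.
#' @return a list of class \code{study_correlation} with elements \code{a}
#'   (marginal non-null probabilities), \code{a_joint} (symmetric matrix of
#'   bootstrap-mean joint probabilities is omitted; the pair EMs feed the
#'   correlations directly), and \code{r} (symmetric correlation matrix with
#'   unit diagonal).
#' @export
study_correlation_matrix <- function(x, models, B = 100L, seed = 1L) {
  Z <- as_zscores(x)
  m <- ncol(Z$values)
  r <- diag(1, m)
  dimnames(r) <- list(colnames(Z$values), colnames(Z$values))
  for (i in seq_len(m - 1L)) {
    for (j in seq(i + 1L, m)) {
      rij <- bootstrap_correlation(Z$values[, i], Z$values[, j],
                                   models[[i]], models[[j]], B = B,
                                   seed = (seed + i * m + j) %% .Machine$integer.max)
      r[i, j] <- rij
      r[j, i] <- rij
    }
  }
  structure(list(a = 1 - vapply(models, function(mo) mo$pi0, numeric(1)),
                 r = r, study_ids = colnames(Z$values)),
            class = "study_correlation")
}

#' Partition studies into clusters from their correlation network
#'
#' Builds the graph with an edge wherever the absolute correlation reaches
#' the threshold, then finds communities with the map-equation (infomap)
#' random-walk algorithm; isolated studies become singleton clusters. Edges
#' carry |r| as weight: on an unweighted graph a modest rate of spurious
#' borderline edges (estimation noise just above the threshold) lets the
#' random walk leak between genuinely distinct blocks and infomap merges
#' them, while the weighted walk, dominated by the strong within-block
#' correlations, recovers the blocks reliably. A connected-components
#' fallback is available (unweighted by nature).
#'
#' @param corr a \code{study_correlation} (or a plain symmetric correlation
#'   matrix).
#' @param edge_threshold absolute-correlation threshold for edge presence
#'   (default 0.1).
#' @param method \code{"infomap"} or \code{"components"}.
#' @param seed RNG seed for the community search.
#' @return an object of class \code{cluster_partition}: a list of integer
#'   vectors of study indices, disjoint and covering 1..m, with the study
#'   labels as names.
#' @export
cluster_studies <- function(corr, edge_threshold = 0.1,
                            method = c("infomap", "components"), seed = 1L) {
  method <- match.arg(method)
  r <- if (inherits(corr, "study_correlation")) corr$r else as.matrix(corr)
  m <- ncol(r)
  adj <- abs(r) * (abs(r) >= edge_threshold)
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE)
  membership <- if (method == "components") {
    igraph::components(g)$membership
  } else {
    set.seed(seed)
    igraph::membership(igraph::cluster_infomap(g))
  }
  ids <- colnames(r)
  clusters <- unname(split(seq_len(m), membership))
  clusters <- lapply(clusters, function(idx) {
    names(idx) <- ids[idx]
    sort(idx)
  })
  # deterministic order: by smallest member
  clusters <- clusters[order(vapply(clusters, min, numeric(1)))]
  structure(clusters, class = "cluster_partition")
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat(sprintf("cluster_partition: %d clusters (sizes %s)\n", length(x),
              paste(sort(lengths(x), decreasing = TRUE), collapse = ", ")))
  invisible(x)
}
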