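# The SCREEN driver: per-cluster configuration EM, per-cluster posteriors of
# the non-null count, and the dynamic-programming merge across independent
# clusters.

#' Posterior non-null-count distribution within one study cluster
#'
#' Estimates a configuration prior for the cluster (unrestricted EM when the
#' full space fits within n_H, the restricted EM otherwise), computes each
#' gene's posterior over the retained configurations — renormalized over the
#' retained mass — and aggregates by the number of non-null entries.
#'
#' @param x a \code{study_matrix} over all studies.
#' @param models list of fitted models for all studies.
#' @param cluster integer vector of study indices forming the cluster.
#' @param n_H configuration memory cap for the cluster EM.
#' @param prior optional \code{configuration_prior} over the cluster's
#'   configurations; skips the EM when supplied (used by oracles and by
#'   callers that estimated the prior already).
#' @return an object of class \code{cluster_count_posterior}: a list with
#'   \code{cluster}, \code{table} (genes x (|C|+1), rows summing to 1, column
#'   c+1 = P(exactly c non-nulls in the cluster)), and \code{prior}.
#' @export
cluster_count_posteriors <- function(x, models, cluster, n_H = 1024L,
                                     prior = NULL) {
  cluster <- sort(as.integer(cluster))
  stopifnot(length(cluster) >= 1L)
  Z <- as_zscores(x)
  sub <- study_matrix(Z$values[, cluster, drop = FALSE], scale = "zscore")
  models_C <- models[cluster]
  if (is.null(prior)) {
    prior <- em_restricted(sub, models_C, n_H = n_H)
  }
  comp <- lik_components(sub, models_C)
  logL <- config_loglik(comp$F0, comp$F1, prior$configs)
  shift <- apply(logL, 1, max)
  W <- exp(logL - shift)
  W <- W * rep(prior$probs, each = nrow(W))
  rs <- pmax(rowSums(W), 1e-300)
  W <- W / rs
  cnt <- rowSums(prior$configs)
  csize <- length(cluster)
  table <- matrix(0, nrow(W), csize + 1L)
  for (c in 0:csize) {
    sel <- which(cnt == c)
    if (length(sel)) table[, c + 1L] <- rowSums(W[, sel, drop = FALSE])
  }
  rownames(table) <- comp$gene_ids
  structure(list(cluster = cluster, table = table, prior = prior),
            class = "cluster_count_posterior")
}

#' Merge per-cluster count posteriors into fdr_k values
#'
#' Under cluster independence the total number of non-null realizations of a
#' gene is the sum of independent per-cluster counts, so the posterior count
#' distributions convolve. The convolution is carried out cluster by cluster
#' (O(k^2 M) per gene) and fdr_k is the total posterior mass on counts below
#' k.
#'
#' @param posteriors list of \code{cluster_count_posterior} over disjoint
#'   clusters.
#' @param k integer vector of replication levels, each at most (total number
#'   of studies) + 1.
#' @param threshold selection threshold.
#' @return an \code{fdr_result}; the full merged count distribution is
#'   attached as \code{attr(, "counts")}.
#' @export
merge_clusters <- function(posteriors, k, threshold = 0.2) {
  stopifnot(length(posteriors) >= 1L)
  idx <- unlist(lapply(posteriors, function(p) p$cluster))
  if (anyDuplicated(idx)) stop("clusters must be disjoint")
  m_total <- length(idx)
  k <- as.integer(k)
  stopifnot(all(k >= 1L), all(k <= m_total + 1L))
  total <- posteriors[[1L]]$table
  gene_ids <- rownames(total)
  for (p in posteriors[-1L]) {
    t2 <- p$table
    newtot <- matrix(0, nrow(total), ncol(total) + ncol(t2) - 1L)
    for (c2 in seq_len(ncol(t2))) {
      cols <- seq_len(ncol(total)) + c2 - 1L
      newtot[, cols] <- newtot[, cols] + total * t2[, c2]
    }
    total <- newtot
  }
  fdr <- sapply(k, function(kk) {
    if (kk > ncol(total)) rep(1, nrow(total))
    else rowSums(total[, seq_len(kk), drop = FALSE])
  })
  out <- fdr_result(gene_ids, k, pmin(as.matrix(fdr), 1), threshold = threshold)
  rownames(total) <- gene_ids
  attr(out, "counts") <- total
  out
}

#' SCREEN: replicability analysis across clustered studies
#'
#' The full pipeline: (1) fit a two-groups model per study (normix with the
#' theoretical null by default) and shrink each non-null density by the
#' study's estimated power; (2) estimate the study-correlation network by
#' bootstrapped pair EMs and partition the studies into clusters; (3) run the
#' configuration EM within each cluster and compute per-gene posteriors of
#' the non-null count; (4) convolve the cluster counts by dynamic programming
#' and report fdr_k per gene with selection at the threshold.
#'
#' @param x a \code{study_matrix} (p-values or z-scores).
#' @param k integer vector of replication levels.
#' @param models optional pre-fitted models (skips stage 1).
#' @param clusters optional \code{cluster_partition} (skips stage 2).
#' @param estimator,null two-groups estimator options, see
#'   \code{\link{fit_study_models}}.
#' @param n_configs configuration memory cap per cluster EM.
#' @param edge_threshold absolute-correlation threshold for network edges.
#' @param bootstrap bootstrap runs per study pair.
#' @param fdr_threshold selection threshold on fdr_k (0.2 by default; a more
#'   permissive 0.4 trades a few false positives for coverage).
#' @param cluster_method community detection method, see
#'   \code{\link{cluster_studies}}.
#' @param seed master seed; all stage seeds derive from it.
#' @param verbose log stage progress to standard error.
#' @return an \code{fdr_result} with the partition, correlation structure,
#'   models and per-cluster posteriors attached as attributes
#'   (\code{"clusters"}, \code{"correlation"}, \code{"models"},
#'   \code{"posteriors"}).
#' @export
screen <- function(x, k = 2L, models = NULL, clusters = NULL,
                   estimator = "normix", null = "theoretical",
                   n_configs = 1024L, edge_threshold = 0.1,
                   bootstrap = 100L, fdr_threshold = 0.2,
                   cluster_method = "infomap", seed = 1L, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[3]
  if (is.null(models)) {
    say("[screen] fitting %d two-groups models (%s, %s null)",
        ncol(x$values), estimator, null)
    models <- fit_study_models(x, estimator = estimator, null = null)
  }
  corr <- NULL
  if (is.null(clusters)) {
    say("[screen] estimating study correlations (B = %d)", bootstrap)
    corr <- study_correlation_matrix(x, models, B = bootstrap, seed = seed)
    clusters <- cluster_studies(corr, edge_threshold = edge_threshold,
                                method = cluster_method, seed = seed)
  }
  say("[screen] %d clusters (sizes %s)", length(clusters),
      paste(sort(lengths(clusters), decreasing = TRUE), collapse = ","))
  posteriors <- lapply(clusters, function(cl) {
    cluster_count_posteriors(x, models, cl, n_H = n_configs)
  })
  say("[screen] merging clusters")
  out <- merge_clusters(posteriors, k, threshold = fdr_threshold)
  attr(out, "clusters") <- clusters
  attr(out, "correlation") <- corr
  attr(out, "models") <- models
  attr(out, "posteriors") <- posteriors
  say("[screen] done in %.1fs", proc.time()[3] - t0)
  out
}

#' SCREEN-ind: exact replicability analysis under study independence
#'
#' Fits the per-study two-groups models and computes the exact fdr_k by the
#' independence dynamic program (each study its own cluster, priors from the
#' fitted pi0 values).
#'
#' @inheritParams screen
#' @return an \code{fdr_result} with the models attached as
#'   \code{attr(, "models")}.
#' @export
screen_ind <- function(x, k = 2L, models = NULL, estimator = "normix",
                       null = "theoretical", fdr_threshold = 0.2) {
  if (is.null(models)) {
    models <- fit_study_models(x, estimator = estimator, null = null)
  }
  out <- fdr_k_independent(x, models, k, threshold = fdr_threshold)
  attr(out, "models") <- models
  out
}
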