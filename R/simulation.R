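# Simulation generators with known ground truth: independent studies
# (sparse per-study effects plus a replicable gene block) and
# block-dependent studies (thresholded equicorrelated Gaussians), with the
# exact generative-model fdr as an oracle.

#' Draw non-null p-values from the two-sided Beta mixture
#'
#' With probability 0.5 from Beta(1, x) (p-values near 0) and otherwise from
#' Beta(x, 1) (p-values near 1, the other tail of a one-sided test).
#' x in \{10, 100, 1000\} gives low-component mean p-values of about 0.1,
#' 0.01 and 0.001.
#'
#' @param x Beta shape parameter, > 1.
#' @param count number of draws.
#' @param low_only draw only the Beta(1, x) (low p-value) component.
#' @return numeric vector of p-values.
#' @export
sample_nonnull_p <- function(x, count, low_only = FALSE) {
  stopifnot(x > 1, count >= 0)
  if (low_only) return(stats::rbeta(count, 1, x))
  low <- stats::runif(count) < 0.5
  ifelse(low, stats::rbeta(count, 1, x), stats::rbeta(count, x, 1))
}

sim_dataset <- function(Pvals, H, params) {
  n <- nrow(Pvals)
  gene_ids <- paste0("gene", seq_len(n))
  study_ids <- paste0("study", seq_len(ncol(Pvals)))
  dimnames(Pvals) <- list(gene_ids, study_ids)
  dimnames(H) <- list(gene_ids, study_ids)
  structure(list(P = study_matrix(Pvals, scale = "pvalue"),
                 H = H, params = params),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("sim_dataset (%s): %d genes x %d studies\n",
              x$params$layout, nrow(x$H), ncol(x$H)))
  invisible(x)
}

#' Simulate independent studies with a replicable gene block
#'
#' In each study an independent random set of genes is non-null; their
#' p-values come from the 50/50 Beta(1,x)/Beta(x,1) mixture and null cells
#' are Uniform(0,1). A block of genes (the first \code{replicable_genes}
#' rows) is additionally made non-null in \code{extra_studies} studies drawn
#' independently per gene, with Beta(1, x) draws only, guaranteeing a set of
#' strongly replicable genes without introducing dependence between any two
#' studies' non-null indicators (a shared extra-study set would correlate
#' those studies and make the scenario no longer independent).
#'
#' @param n,m genes and studies.
#' @param per_study_nonnull non-null genes drawn (without replacement) per
#'   study.
#' @param replicable_genes size of the replicable block.
#' @param extra_studies number of studies the block is planted in.
#' @param x Beta shape parameter of the non-null mixture.
#' @param seed RNG seed.
#' @return a \code{sim_dataset} with elements \code{P} (the p-value
#'   \code{study_matrix}), \code{H} (the true 0/1 configuration matrix) and
#'   \code{params}.
#' @export
simulate_independent <- function(n = 5000L, m = 20L, per_study_nonnull = 300L,
                                 replicable_genes = 50L, extra_studies = 5L,
                                 x = 100, seed = 1L) {
  stopifnot(extra_studies <= m, per_study_nonnull <= n, replicable_genes <= n)
  set.seed(seed)
  H <- matrix(0L, n, m)
  for (j in seq_len(m)) {
    H[sample.int(n, per_study_nonnull), j] <- 1L
  }
  P <- matrix(stats::runif(n * m), n, m)
  nonnull <- H == 1L
  P[nonnull] <- sample_nonnull_p(x, sum(nonnull))
  if (replicable_genes > 0L && extra_studies > 0L) {
    for (i in seq_len(replicable_genes)) {
      rs <- sample.int(m, extra_studies)
      H[i, rs] <- 1L
      P[i, rs] <- sample_nonnull_p(x, extra_studies, low_only = TRUE)
    }
  }
  sim_dataset(P, H, list(layout = "independent", n = n, m = m,
                         per_study_nonnull = per_study_nonnull,
                         replicable_genes = replicable_genes,
                         extra_studies = extra_studies, x = x, seed = seed))
}

#' Simulate studies in independent correlated clusters
#'
#' An auxiliary matrix A has rows drawn from N(0, Sigma) where Sigma is
#' block-exchangeable: M independent blocks of \code{cluster_size} studies
#' with within-block correlation r (generated via a one-factor
#' representation). A cell is non-null when A exceeds the fixed
#' \code{quantile} of the standard normal, so each study's expected non-null
#' count is n(1 - quantile). P-values are then drawn as in the independent
#' scenario.
#'
#' @param n genes.
#' @param M number of study clusters.
#' @param cluster_size studies per cluster.
#' @param r within-cluster correlation, 0 <= r < 1.
#' @param x Beta shape parameter of the non-null mixture.
#' @param quantile threshold quantile of the standard normal (0.94 gives a
#'   6\% non-null rate: 300 of 5000 genes per study).
#' @param seed RNG seed.
#' @return a \code{sim_dataset}; \code{params$blocks} holds the true
#'   partition labels.
#' @export
simulate_clustered <- function(n = 5000L, M = 4L, cluster_size = 10L,
                               r = 0.8, x = 100, quantile = 0.94, seed = 1L) {
  if (r < 0 || r >= 1) stop("within-cluster correlation must be in [0, 1)")
  set.seed(seed)
  m <- M * cluster_size
  tau <- stats::qnorm(quantile)
  A <- matrix(0, n, m)
  for (b in seq_len(M)) {
    W <- stats::rnorm(n)
    E <- matrix(stats::rnorm(n * cluster_size), n, cluster_size)
    A[, (b - 1L) * cluster_size + seq_len(cluster_size)] <-
      sqrt(r) * W + sqrt(1 - r) * E
  }
  H <- (A >= tau) * 1L
  P <- matrix(stats::runif(n * m), n, m)
  nonnull <- H == 1L
  P[nonnull] <- sample_nonnull_p(x, sum(nonnull))
  sim_dataset(P, H, list(layout = "clustered", n = n, M = M,
                         cluster_size = cluster_size, r = r, x = x,
                         quantile = quantile, seed = seed,
                         blocks = rep(seq_len(M), each = cluster_size)))
}

#' Exact fdr_k under the clustered generative model
#'
#' Ground-truth oracle for \code{\link{simulate_clustered}} data: computes
#' each gene's true posterior probability of fewer than k non-null
#' realizations under the model that actually generated the data. The
#' exchangeable within-cluster configuration prior is obtained by
#' integrating the one-factor representation over the shared factor
#' (trapezoidal quadrature); the likelihood uses the true Uniform null and
#' Beta-mixture non-null densities; per-cluster count posteriors are then
#' convolved across the independent clusters.
#'
#' @param sim a \code{sim_dataset} from \code{\link{simulate_clustered}}.
#' @param k integer vector of replication levels.
#' @return matrix of true fdr_k values, genes x length(k).
#' @export
oracle_fdr_clustered <- function(sim, k) {
  stopifnot(inherits(sim, "sim_dataset"), sim$params$layout == "clustered")
  pars <- sim$params
  csize <- pars$cluster_size
  tau <- stats::qnorm(pars$quantile)
  # prior weight of any single configuration with c non-nulls in a cluster
  w <- seq(-8, 8, length.out = 4001L)
  dw <- w[2] - w[1]
  pw <- if (pars$r > 0) {
    stats::pnorm((sqrt(pars$r) * w - tau) / sqrt(1 - pars$r))
  } else {
    rep(1 - pars$quantile, length(w))
  }
  phi_w <- stats::dnorm(w)
  w_c <- vapply(0:csize, function(c) {
    sum(phi_w * pw^c * (1 - pw)^(csize - c)) * dw
  }, numeric(1))
  # per-cluster posterior count distributions with the true densities
  pv <- sim$P$values
  f1 <- 0.5 * stats::dbeta(pv, 1, pars$x) + 0.5 * stats::dbeta(pv, pars$x, 1)
  posts <- lapply(seq_len(pars$M), function(b) {
    cols <- (b - 1L) * csize + seq_len(csize)
    T <- count_dp(matrix(1, nrow(pv), csize), f1[, cols, drop = FALSE])
    J <- sweep(T, 2, w_c, "*")
    J / rowSums(J)
  })
  total <- posts[[1L]]
  for (b in seq_len(pars$M)[-1L]) {
    t2 <- posts[[b]]
    newtot <- matrix(0, nrow(total), ncol(total) + ncol(t2) - 1L)
    for (c2 in seq_len(ncol(t2))) {
      cols <- seq_len(ncol(total)) + c2 - 1L
      newtot[, cols] <- newtot[, cols] + total * t2[, c2]
    }
    total <- newtot
  }
  out <- sapply(as.integer(k), function(kk) {
    rowSums(total[, seq_len(min(kk, ncol(total))), drop = FALSE])
  })
  out <- pmin(pmax(as.matrix(out), 0), 1)
  dimnames(out) <- list(rownames(pv), paste0("fdr_k", k))
  out
}
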