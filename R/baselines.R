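# Comparison methods: Fisher meta-analysis with BH, per-study BH counting,
# and the expected-non-null-count (tdr sum) statistic.

#' Fisher's meta-analysis with BH correction
#'
#' Combines each gene's p-values with Fisher's statistic
#' X = -2 sum_j log p_j, refers X to a chi-square with 2m degrees of freedom,
#' and applies the Benjamini-Hochberg step-up procedure across genes.
#' Selection at q <= 0.1 by default.
#'
#' @param P a \code{study_matrix} on the p-value scale.
#' @param q_threshold BH q-value selection threshold.
#' @return a list of class \code{baseline_result} with \code{statistic} (the
#'   combined p-value), \code{q} (BH q-values), \code{selected}.
#' @export
fisher_meta <- function(P, q_threshold = 0.1) {
  stopifnot(inherits(P, "study_matrix"), P$scale == "pvalue")
  pv <- pmin(pmax(P$values, 1e-300), 1)  # clip before logging
  X <- -2 * rowSums(log(pv))
  combined <- stats::pchisq(X, df = 2 * ncol(pv), lower.tail = FALSE)
  q <- stats::p.adjust(combined, method = "BH")
  structure(list(gene_ids = rownames(pv), method = "fisher",
                 chisq = X, statistic = combined, q = q,
                 selected = q <= q_threshold),
            class = "baseline_result")
}

#' Per-study BH counting
#'
#' Applies the BH correction within each study and counts, per gene, the
#' studies with q-value at or below the threshold. Genes are called
#' k-replicable when the count reaches k.
#'
#' @param P a \code{study_matrix} on the p-value scale.
#' @param q_threshold per-study BH threshold (default 0.1).
#' @param k optional replication level for the selection calls.
#' @return a \code{baseline_result} with integer \code{statistic} in [0, m].
#' @export
bh_count <- function(P, q_threshold = 0.1, k = NULL) {
  stopifnot(inherits(P, "study_matrix"), P$scale == "pvalue")
  Q <- apply(P$values, 2, stats::p.adjust, method = "BH")
  counts <- rowSums(Q <= q_threshold)
  structure(list(gene_ids = rownames(P$values), method = "bh_count",
                 statistic = counts,
                 selected = if (is.null(k)) NULL else counts >= k),
            class = "baseline_result")
}

#' Expected non-null count from marginal tdr values
#'
#' Sums, per gene, the per-study local true discovery rates
#' 1 - P(h_ij = 0 | Z_ij): a (biased) estimator of the expected number of
#' non-null realizations. Under the independence product prior this equals
#' the posterior expectation of the configuration weight.
#'
#' @param x a \code{study_matrix}.
#' @param models list of fitted models, one per study.
#' @param k optional replication level for the selection calls
#'   (statistic >= k).
#' @return a \code{baseline_result} with \code{statistic} in [0, m].
#' @export
exp_count <- function(x, models = NULL, k = NULL) {
  if (is.null(models)) models <- fit_study_models(x)
  comp <- lik_components(x, models)
  G0 <- sweep(comp$F0, 2, comp$pi0, "*")
  G1 <- sweep(comp$F1, 2, 1 - comp$pi0, "*")
  f <- pmax(G0 + G1, 1e-300)
  stat <- rowSums(G1 / f)
  structure(list(gene_ids = comp$gene_ids, method = "exp_count",
                 statistic = stat,
                 selected = if (is.null(k)) NULL else stat >= k),
            class = "baseline_result")
}

#' @export
print.baseline_result <- function(x, ...) {
  cat(sprintf("baseline_result (%s): %d genes%s\n", x$method,
              length(x$gene_ids),
              if (!is.null(x$selected)) sprintf(", %d selected", sum(x$selected))
              else ""))
  invisible(x)
}
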