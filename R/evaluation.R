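# Scoring method output against simulation ground truth, direction calls,
# and rank comparisons against meta-analysis.

#' Empirical FDP and Jaccard score of a selection against ground truth
#'
#' The truth set for level k is the genes with at least k non-null entries
#' in the true configuration matrix. FDP is the fraction of selected genes
#' outside the truth set (0 for an empty selection, by convention); Jaccard
#' is intersection over union.
#'
#' @param selected character vector of selected gene ids (or logical/integer
#'   index into the rows of \code{H_true}).
#' @param H_true true 0/1 configuration matrix with gene ids as row names.
#' @param k replication level defining the truth set.
#' @return named numeric vector \code{c(FDP = ..., jaccard = ...)}.
#' @export
fdp_jaccard <- function(selected, H_true, k) {
  ids <- rownames(H_true)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(H_true)))
  if (is.logical(selected) || is.numeric(selected)) selected <- ids[selected]
  truth <- ids[rowSums(H_true) >= k]
  fdp <- if (length(selected) == 0L) 0 else {
    length(setdiff(selected, truth)) / length(selected)
  }
  uni <- union(selected, truth)
  jac <- if (length(uni) == 0L) 0 else length(intersect(selected, truth)) / length(uni)
  c(FDP = fdp, jaccard = jac)
}

#' Direction calls from signed statistics
#'
#' For each gene, counts positive and negative statistics among the studies
#' whose p-value passes \code{p_cut}, and labels the gene "up" when the
#' up/down ratio is at least \code{ratio}, "down" when it is at most
#' 1/\code{ratio}, and "mixed" otherwise. A zero denominator counts as an
#' infinite ratio; genes with no study passing the cut are labelled mixed
#' with a warning.
#'
#' @param signed_stats \code{study_matrix} (or matrix) of signed statistics.
#' @param p \code{study_matrix} (or matrix) of p-values, aligned with
#'   \code{signed_stats}.
#' @param p_cut significance cut for an event (default 0.01).
#' @param ratio consistency ratio (default 3).
#' @return factor of labels \code{up}/\code{down}/\code{mixed} per gene.
#' @export
direction_calls <- function(signed_stats, p, p_cut = 0.01, ratio = 3) {
  S <- if (inherits(signed_stats, "study_matrix")) signed_stats$values else as.matrix(signed_stats)
  P <- if (inherits(p, "study_matrix")) p$values else as.matrix(p)
  stopifnot(all(dim(S) == dim(P)))
  pass <- P <= p_cut
  up <- rowSums(S > 0 & pass)
  down <- rowSums(S < 0 & pass)
  lab <- rep("mixed", nrow(S))
  none <- up + down == 0
  if (any(none)) warning(sum(none), " gene(s) with no study passing p_cut; labelled mixed")
  is_up <- !none & (up >= ratio * down)     # down = 0 acts as infinite ratio
  is_down <- !none & (down >= ratio * up)
  lab[is_up] <- "up"
  lab[is_down] <- "down"
  out <- factor(lab, levels = c("up", "down", "mixed"))
  names(out) <- rownames(S)
  out
}

#' Spearman rank agreement between an fdr ranking and Fisher's meta-analysis
#'
#' Both methods rank genes from most to least significant (ascending fdr_k,
#' ascending combined p); ties get average ranks.
#'
#' @param fdr_res an \code{fdr_result}.
#' @param fisher_res a \code{baseline_result} from \code{\link{fisher_meta}}
#'   over the same gene universe.
#' @param k which replication level of \code{fdr_res} to rank by.
#' @return Spearman's rho in [-1, 1].
#' @export
rank_vs_fisher <- function(fdr_res, fisher_res, k = fdr_res$k[1]) {
  stopifnot(inherits(fdr_res, "fdr_result"))
  idx <- match(fdr_res$gene_ids, fisher_res$gene_ids)
  stopifnot(!anyNA(idx))
  stats::cor(fdr_res$fdr[, match(k, fdr_res$k)], fisher_res$statistic[idx],
             method = "spearman")
}

#' Adjusted Rand index between two partitions
#'
#' Standard chance-corrected agreement between two labelings of the same
#' items; 1 means identical partitions.
#'
#' @param a,b label vectors of equal length (or \code{cluster_partition}
#'   objects over the same study universe).
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  to_labels <- function(x) {
    if (inherits(x, "cluster_partition")) {
      lab <- integer(sum(lengths(x)))
      for (i in seq_along(x)) lab[x[[i]]] <- i
      lab
    } else x
  }
  a <- to_labels(a); b <- to_labels(b)
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  ch2 <- function(v) sum(v * (v - 1) / 2)
  sum_ij <- ch2(as.vector(tab))
  sum_a <- ch2(rowSums(tab))
  sum_b <- ch2(colSums(tab))
  n2 <- ch2(length(a))
  expected <- sum_a * sum_b / n2
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}

#' Score one or more fdr results against simulation ground truth
#'
#' Convenience wrapper producing a per-k table of FDP, Jaccard and selection
#' counts for an \code{fdr_result} on a simulated dataset.
#'
#' @param fdr_res an \code{fdr_result}.
#' @param H_true true configuration matrix.
#' @return data frame with columns k, n_selected, FDP, jaccard.
#' @export
evaluate_result <- function(fdr_res, H_true) {
  stopifnot(inherits(fdr_res, "fdr_result"))
  rows <- lapply(seq_along(fdr_res$k), function(i) {
    sel <- fdr_res$gene_ids[fdr_res$selected[, i]]
    sc <- fdp_jaccard(sel, H_true, fdr_res$k[i])
    data.frame(k = fdr_res$k[i], n_selected = length(sel),
               FDP = sc[["FDP"]], jaccard = sc[["jaccard"]])
  })
  do.call(rbind, rows)
}
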