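#' Per-gene fdr_k results
#'
#' Container for the output of the replicability drivers: one fdr column per
#' requested k, plus the selection calls at a local-fdr threshold.
#'
#' @param gene_ids character vector of gene labels.
#' @param k integer vector of requested replication levels.
#' @param fdr numeric matrix, genes x length(k), values in [0,1].
#' @param threshold selection threshold on the local fdr (default 0.2).
#' @param is_bound \code{TRUE} when the values are upper bounds rather than
#'   exact posteriors.
#' @return an object of class \code{fdr_result} with a \code{selected}
#'   logical matrix satisfying \code{selected == (fdr <= threshold)}.
#' @export
fdr_result <- function(gene_ids, k, fdr, threshold = 0.2, is_bound = FALSE) {
  fdr <- as.matrix(fdr)
  stopifnot(length(gene_ids) == nrow(fdr), length(k) == ncol(fdr),
            all(fdr >= -1e-12), all(fdr <= 1 + 1e-12))
  fdr <- pmin(pmax(fdr, 0), 1)
  dimnames(fdr) <- list(gene_ids, paste0("fdr_k", k))
  structure(list(gene_ids = gene_ids, k = as.integer(k), fdr = fdr,
                 threshold = threshold, is_bound = is_bound,
                 selected = fdr <= threshold),
            class = "fdr_result")
}

#' @export
print.fdr_result <- function(x, ...) {
  cat(sprintf("fdr_result: %d genes, k = %s%s, threshold %.2f\n",
              length(x$gene_ids), paste(x$k, collapse = ","),
              if (x$is_bound) " (upper bounds)" else "", x$threshold))
  cat("selected per k:", paste(colSums(x$selected), collapse = ", "), "\n")
  invisible(x)
}

#' Extract the selected gene set for one k
#' @param x an \code{fdr_result}.
#' @param k which replication level.
#' @return character vector of selected gene ids.
#' @export
selected_genes <- function(x, k) {
  stopifnot(inherits(x, "fdr_result"), k %in% x$k)
  x$gene_ids[x$selected[, match(k, x$k)]]
}

#' Write fdr results to TSV (one row per gene, fdr and selection per k)
#' @param x an \code{fdr_result}.
#' @param path output path.
#' @export
write_fdr_results <- function(x, path) {
  stopifnot(inherits(x, "fdr_result"))
  df <- data.frame(gene = x$gene_ids, stringsAsFactors = FALSE)
  for (i in seq_along(x$k)) {
    df[[paste0("fdr_k", x$k[i])]] <- signif(x$fdr[, i], 6)
    df[[paste0("selected_k", x$k[i])]] <- x$selected[, i]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
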