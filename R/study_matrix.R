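#' Construct a genes-by-studies matrix of p-values or z-scores
#'
#' The basic input container: an \code{n x m} numeric matrix with gene
#' identifiers as row names and study identifiers as column names, together
#' with a declaration of the scale of its cells.
#'
#' @param values numeric matrix, genes in rows, studies in columns.
#' @param scale \code{"pvalue"} (cells strictly in (0,1) after clipping) or
#'   \code{"zscore"}.
#' @param gene_ids,study_ids optional label vectors; default to the dimnames
#'   of \code{values}, or \code{gene1..geneN} / \code{study1..studyM}.
#' @return an object of class \code{study_matrix}: a list with elements
#'   \code{values}, \code{scale}.
#' @export
study_matrix <- function(values, scale = c("pvalue", "zscore"),
                         gene_ids = NULL, study_ids = NULL) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("study_matrix values must be numeric")
  if (nrow(values) < 2L) stop("study_matrix needs at least 2 genes")
  if (ncol(values) < 1L) stop("study_matrix needs at least 1 study")
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing cell at gene row %d, study column %d", bad[1], bad[2]))
  }
  if (is.null(gene_ids)) gene_ids <- rownames(values)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(values)))
  if (is.null(study_ids)) study_ids <- colnames(values)
  if (is.null(study_ids)) study_ids <- paste0("study", seq_len(ncol(values)))
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene id: ", gene_ids[anyDuplicated(gene_ids)])
  }
  dimnames(values) <- list(gene_ids, study_ids)
  if (scale == "pvalue") {
    if (any(values < 0 | values > 1)) {
      bad <- which(values < 0 | values > 1, arr.ind = TRUE)[1L, ]
      stop(sprintf("p-value out of [0,1] for gene '%s', study '%s'",
                   gene_ids[bad[1]], study_ids[bad[2]]))
    }
    values <- pmin(pmax(values, 1e-15), 1 - 1e-15)
  }
  structure(list(values = values, scale = scale), class = "study_matrix")
}

#' @export
print.study_matrix <- function(x, ...) {
  cat(sprintf("study_matrix: %d genes x %d studies (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @export
dim.study_matrix <- function(x) dim(x$values)

#' Convert a p-value matrix to one-tailed z-scores
#'
#' Applies \code{z = qnorm(1 - p)} cellwise after clipping p into
#' \code{[1e-15, 1 - 1e-15]}, so p near 0 maps to large positive z and p
#' near 1 to large negative z. For one-tailed input p-values both tails of
#' the z-scale then carry non-null signal, which the absolute-scale
#' two-groups model treats symmetrically.
#'
#' @param P a \code{study_matrix} on the p-value scale.
#' @return a \code{study_matrix} on the z-score scale.
#' @export
pvals_to_zscores <- function(P) {
  stopifnot(inherits(P, "study_matrix"))
  if (P$scale != "pvalue") stop("pvals_to_zscores expects a p-value matrix")
  p <- pmin(pmax(P$values, 1e-15), 1 - 1e-15)
  z <- stats::qnorm(1 - p)
  study_matrix(z, scale = "zscore")
}

#' Read a genes-by-studies matrix from a TSV file
#'
#' Expects a header row of study identifiers and a first column of gene
#' identifiers; all remaining cells numeric.
#'
#' @param path file path.
#' @param scale declared scale of the cells.
#' @return a \code{study_matrix}.
#' @export
read_study_matrix <- function(path, scale = c("pvalue", "zscore")) {
  scale <- match.arg(scale)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected a gene-id column plus at least one study column")
  ids <- as.character(df[[1L]])
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate gene id: ", dup[1L])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1L, drop = FALSE], 2, as.numeric))),
                 arr.ind = TRUE)
    stop(sprintf("non-numeric cell at line %d", bad[1L, 1L] + 1L))
  }
  rownames(vals) <- ids
  study_matrix(vals, scale = scale)
}

#' Write a study matrix to TSV
#' @param x a \code{study_matrix}.
#' @param path output file path.
#' @export
write_study_matrix <- function(x, path) {
  stopifnot(inherits(x, "study_matrix"))
  df <- data.frame(gene = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# coerce input to a z-scale study_matrix (drivers accept either scale)
as_zscores <- function(x) {
  stopifnot(inherits(x, "study_matrix"))
  if (x$scale == "pvalue") pvals_to_zscores(x) else x
}
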