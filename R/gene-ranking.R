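#' Per-gene importance scores
#'
#' The importance of gene i is the Euclidean norm of the i-th row of the
#' learned projection matrix: genes whose rows survive the l2,1 penalty
#' carry the projection onto the pseudo-label space.
#'
#' @param P Numeric m x c projection matrix with finite entries.
#' @return Numeric vector of m nonnegative scores.
#' @export
gene_scores <- function(P) {
  P <- as.matrix(P)
  if (anyNA(P) || !all(is.finite(P)))
    stop("projection matrix contains non-finite entries", call. = FALSE)
  sqrt(rowSums(P^2))
}

#' Select the top-scoring genes
#'
#' Deterministic top-`n_select` selection: genes are ordered by descending
#' score with ties broken toward the smaller gene index.
#'
#' @param scores Numeric vector of nonnegative gene scores.
#' @param n_select Number of genes to keep, between 1 and `length(scores)`.
#' @param gene_ids Optional gene identifiers carried into the result.
#' @return A list of class `gene_ranking` with elements `scores`, `order`
#'   (full descending-score permutation), `selected` (first `n_select`
#'   indices of `order`) and `gene_ids`.
#' @export
select_top_genes <- function(scores, n_select, gene_ids = NULL) {
  if (anyNA(scores) || any(!is.finite(scores)))
    stop("scores must be finite", call. = FALSE)
  m <- length(scores)
  n_select <- as.integer(n_select)
  if (n_select < 1L || n_select > m)
    stop("n_select must be between 1 and ", m, ", got ", n_select,
         call. = FALSE)
  ord <- order(-scores, seq_len(m))
  structure(
    list(scores = scores, order = ord, selected = ord[seq_len(n_select)],
         gene_ids = gene_ids),
    class = "gene_ranking")
}

#' Ranks of all genes in a ranking
#'
#' @param ranking A [select_top_genes()] result.
#' @return Integer vector: `rank[i]` is the rank (1 = best) of gene i.
#' @export
gene_ranks <- function(ranking) {
  stopifnot(inherits(ranking, "gene_ranking"))
  rk <- integer(length(ranking$order))
  rk[ranking$order] <- seq_along(ranking$order)
  rk
}

#' Subset a dataset to the selected genes
#'
#' @param data An [expression_dataset()].
#' @param ranking A [select_top_genes()] result whose indices address
#'   `data`'s genes.
#' @param order Keep the selected genes in their `"original"` matrix order
#'   (default) or in `"ranked"` (descending-score) order.
#' @return An [expression_dataset()] with only the selected genes; the
#'   sample axis is untouched.
#' @export
subset_expression <- function(data, ranking,
                              order = c("original", "ranked")) {
  order <- match.arg(order)
  stopifnot(inherits(data, "expression_dataset"),
            inherits(ranking, "gene_ranking"))
  idx <- ranking$selected
  if (any(idx < 1L | idx > nrow(data$values)))
    stop("selected index out of range", call. = FALSE)
  if (order == "original") idx <- sort(idx)
  # built directly: a selected subset may legitimately hold a single gene,
  # below the >= 2 floor the constructor enforces for analysis inputs
  values <- data$values[idx, , drop = FALSE]
  dimnames(values) <- list(data$gene_ids[idx], data$sample_ids)
  structure(
    list(values = values, gene_ids = data$gene_ids[idx],
         sample_ids = data$sample_ids, labels = data$labels),
    class = "expression_dataset")
}

#' Rank genes from a fitted model
#'
#' Convenience wrapper: scores the projection of a fitted model and selects
#' the top `n_select` genes (default from the fit's configuration).
#'
#' @param fit A [g3cs_fit()] result.
#' @param n_select Number of genes to keep.
#' @return A `gene_ranking`.
#' @export
rank_genes <- function(fit, n_select = fit$config$n_select) {
  stopifnot(inherits(fit, "g3cs_fit"))
  n_select <- min(n_select, length(fit$gene_ids))
  select_top_genes(gene_scores(fit$P), n_select, gene_ids = fit$gene_ids)
}
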