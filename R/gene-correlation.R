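#' Gene-pair covariance matrix
#'
#' Computes the m x m covariance matrix across samples: entry (i, j) is the
#' unbiased covariance (denominator n - 1) between gene i's and gene j's
#' expression profiles. A constant gene contributes a zero row and column.
#'
#' @param data An [expression_dataset()] with at least 2 samples.
#' @return A list of class `gene_covariance` with elements `M` (symmetric
#'   positive-semidefinite m x m matrix) and `gene_means` (per-gene average
#'   expression).
#' @export
covariance_matrix <- function(data) {
  stopifnot(inherits(data, "expression_dataset"))
  X <- data$values
  n <- ncol(X)
  if (n < 2L)
    stop("covariance undefined for fewer than 2 samples", call. = FALSE)
  mu <- rowMeans(X)
  Xc <- X - mu
  M <- tcrossprod(Xc) / (n - 1)
  M <- (M + t(M)) / 2  # kill rounding asymmetry
  structure(list(M = M, gene_means = mu), class = "gene_covariance")
}

#' Adjusted gene correlation matrix
#'
#' Aggregates each gene's covariance with every other gene so that the
#' quadratic penalty on the projection matrix discourages selecting mutually
#' redundant genes. Two readings of the adjustment are provided:
#'
#' * `mode = "printed"` (default): the diagonal keeps the gene variances,
#'   and every off-diagonal entry in row i is replaced by the row sum of
#'   covariances excluding the diagonal, `sum_{k != i} M[i, k]`.
#' * `mode = "diag-rowsum"`: the off-diagonal covariances are kept and the
#'   diagonal (self-covariance, meaningless as a redundancy signal) is
#'   replaced by that same off-diagonal row sum.
#'
#' The printed form is asymmetric; since the penalty `Tr(P' Mbar P)` only
#' senses the symmetric part, `symmetrize = TRUE` (default) replaces the
#' result by `(Mbar + Mbar') / 2` so the penalty gradient `2 Mbar P` is
#' exact.
#'
#' @param cov A [covariance_matrix()] result.
#' @param mode Adjustment reading, see above.
#' @param symmetrize Replace the result by its symmetric part (default TRUE).
#' @return A list of class `adjusted_correlation` with elements `M_bar`,
#'   `mode` and `symmetrized`.
#' @export
adjust_correlation <- function(cov, mode = c("printed", "diag-rowsum"),
                               symmetrize = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(cov, "gene_covariance"))
  M <- cov$M
  m <- nrow(M)
  offsum <- rowSums(M) - diag(M)
  if (mode == "printed") {
    M_bar <- matrix(offsum, m, m)  # row i constant = sum_{k != i} M[i, k]
    diag(M_bar) <- diag(M)
  } else {
    M_bar <- M
    diag(M_bar) <- offsum
  }
  if (symmetrize) M_bar <- (M_bar + t(M_bar)) / 2
  dimnames(M_bar) <- dimnames(M)
  structure(list(M_bar = M_bar, mode = mode, symmetrized = symmetrize),
            class = "adjusted_correlation")
}

#' Redundancy penalty of a projection matrix
#'
#' Evaluates `Tr(P' Mbar P)`, the quadratic form that the solver uses to
#' push correlated (redundant) genes out of the selection. The value is
#' invariant under replacing `Mbar` by its symmetric part.
#'
#' @param P Numeric m x c matrix.
#' @param adj An [adjust_correlation()] result with matching dimension.
#' @return A scalar.
#' @export
correlation_penalty <- function(P, adj) {
  stopifnot(inherits(adj, "adjusted_correlation"))
  P <- as.matrix(P)
  if (nrow(P) != nrow(adj$M_bar))
    stop("P has ", nrow(P), " rows but the adjusted correlation is ",
         nrow(adj$M_bar), " x ", ncol(adj$M_bar), call. = FALSE)
  sum(P * (adj$M_bar %*% P))
}
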