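#' k-nearest-neighbour Gaussian similarity graph over samples
#'
#' Connects each sample to its k nearest neighbours (Euclidean distance on
#' the raw sample columns) and weights each edge with the heat kernel
#' `exp(-||x_i - x_j||^2 / (2 t^2))`. The graph is symmetrized with the OR
#' rule: an edge exists when either endpoint lists the other among its k
#' nearest neighbours. A sample is never its own neighbour and the diagonal
#' is zero. Ties at the k-th distance are broken toward the smaller sample
#' index.
#'
#' @param data An [expression_dataset()].
#' @param k Neighbour count, must be smaller than the number of samples.
#' @param t Kernel width, positive.
#' @return A list of class `similarity_graph` with elements `S` (symmetric
#'   n x n matrix, entries in \[0, 1\], zero diagonal), `k` and `t`.
#' @export
knn_similarity <- function(data, k = 5L, t = 0.5) {
  stopifnot(inherits(data, "expression_dataset"), t > 0)
  X <- data$values
  n <- ncol(X)
  k <- as.integer(k)
  if (k >= n)
    stop("k (", k, ") must be smaller than the number of samples (", n, ")",
         call. = FALSE)
  d2 <- as.matrix(stats::dist(t(X)))^2
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    nb <- others[order(d2[i, others], others)][seq_len(k)]
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj)
  S <- exp(-d2 / (2 * t^2)) * adj
  diag(S) <- 0
  dimnames(S) <- list(data$sample_ids, data$sample_ids)
  structure(list(S = S, k = k, t = t), class = "similarity_graph")
}

#' Unnormalized graph Laplacian
#'
#' Builds `L = D - S` where `D` is the diagonal degree matrix of the
#' similarity graph. Every row of `L` sums to zero and `L` is positive
#' semidefinite.
#'
#' @param graph A [knn_similarity()] result, or any symmetric nonnegative
#'   similarity matrix wrapped as one.
#' @return A list of class `graph_laplacian` with elements `L` and `D`.
#' @export
graph_laplacian <- function(graph) {
  stopifnot(inherits(graph, "similarity_graph"))
  S <- graph$S
  if (!isSymmetric(unname(S), tol = 1e-10))
    stop("similarity matrix must be symmetric", call. = FALSE)
  D <- diag(rowSums(S), nrow(S))
  L <- D - S
  dimnames(L) <- dimnames(S)
  structure(list(L = L, D = D), class = "graph_laplacian")
}

#' Laplacian quadratic form
#'
#' Evaluates `Tr(Z' L Z)`, the smoothness of the relaxed cluster indicators
#' over the sample graph; equal to the pairwise sum
#' `1/2 * sum_ij ||z_i - z_j||^2 S_ij`.
#'
#' @param Z Numeric n x c matrix of indicator rows, one per sample.
#' @param lap A [graph_laplacian()] result.
#' @return A nonnegative scalar (up to numerical tolerance).
#' @export
laplacian_quadratic <- function(Z, lap) {
  stopifnot(inherits(lap, "graph_laplacian"))
  Z <- as.matrix(Z)
  if (nrow(Z) != nrow(lap$L))
    stop("Z has ", nrow(Z), " rows but the Laplacian is ",
         nrow(lap$L), " x ", ncol(lap$L), call. = FALSE)
  sum(Z * (lap$L %*% Z))
}
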