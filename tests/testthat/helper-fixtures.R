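# Shared fixtures and independent brute-force oracles for the test suite.

random_dataset <- function(m, n, seed) {
  set.seed(seed)
  expression_dataset(matrix(rnorm(m * n), m, n),
                     gene_ids = paste0("g", seq_len(m)),
                     sample_ids = paste0("s", seq_len(n)))
}

# covariance by the definition, two explicit index loops
cov_bruteforce <- function(X) {
  m <- nrow(X); n <- ncol(X)
  mu <- rowMeans(X)
  M <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m))
    M[i, j] <- sum((X[i, ] - mu[i]) * (X[j, ] - mu[j])) / (n - 1)
  M
}

# the two adjustment readings, by explicit loops
adjust_bruteforce <- function(M, mode) {
  m <- nrow(M)
  Mb <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    offsum <- sum(M[i, setdiff(seq_len(m), i)])
    Mb[i, j] <- if (mode == "printed") {
      if (i == j) M[i, i] else offsum
    } else {
      if (i == j) offsum else M[i, j]
    }
  }
  Mb
}

# graph smoothness as the pairwise double sum
lapquad_bruteforce <- function(Z, S) {
  n <- nrow(Z)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    tot <- tot + sum((Z[i, ] - Z[j, ])^2) * S[i, j]
  tot / 2
}

# random orthogonal c x c matrix via QR
random_orthogonal <- function(c) {
  qr.Q(qr(matrix(rnorm(c * c), c, c)))
}

# wrap a symmetric similarity matrix for graph_laplacian()
as_similarity_graph <- function(S, k = NA, t = NA) {
  structure(list(S = S, k = k, t = t), class = "similarity_graph")
}
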