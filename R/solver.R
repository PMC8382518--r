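#' l2,1 reweighting matrix
#'
#' Diagonal matrix with `G[i, i] = 1 / (2 * max(||P_row_i||_2, epsilon))`.
#' Reweighted least squares with this matrix majorizes the l2,1 norm of the
#' projection; the floor `epsilon` keeps entries finite when a row has been
#' driven to zero.
#'
#' @param P Numeric m x c matrix.
#' @param epsilon Positive row-norm floor.
#' @return Diagonal m x m matrix with entries in (0, 1 / (2 * epsilon)].
#' @export
compute_G <- function(P, epsilon = 1e-8) {
  stopifnot(epsilon > 0)
  P <- as.matrix(P)
  rn <- sqrt(rowSums(P^2))
  diag(1 / (2 * pmax(rn, epsilon)), nrow(P))
}

#' Closed-form projection update
#'
#' Solves the normal equations `(X X' + alpha G + beta Mbar) P = X Z F'` of
#' the reweighted P subproblem. When the system is numerically singular
#' (possible with `alpha = beta = 0`) a small ridge is added and a warning
#' is raised.
#'
#' @param X Genes x samples expression matrix.
#' @param Z Nonnegative n x c indicator matrix.
#' @param F_mat c x c factor matrix.
#' @param G Diagonal m x m reweighting matrix from [compute_G()].
#' @param adj [adjust_correlation()] result (its symmetric part enters the
#'   system); may be `NULL` when `beta = 0`.
#' @param alpha,beta Nonnegative weights.
#' @return The m x c solution matrix.
#' @export
update_P <- function(X, Z, F_mat, G, adj = NULL, alpha = 0, beta = 0) {
  X <- as.matrix(X)
  m <- nrow(X)
  A <- tcrossprod(X)
  if (alpha > 0) A <- A + alpha * G
  if (beta > 0) {
    stopifnot(inherits(adj, "adjusted_correlation"))
    Ms <- adj$M_bar
    if (!adj$symmetrized) Ms <- (Ms + t(Ms)) / 2
    A <- A + beta * Ms
  }
  B <- X %*% Z %*% t(F_mat)
  P <- tryCatch(solve(A, B), error = function(e) NULL)
  if (is.null(P) || !all(is.finite(P))) {
    ridge <- 1e-10 * max(mean(abs(diag(A))), 1)
    warning("singular P system; ridge stabilization applied", call. = FALSE)
    repeat {
      P <- tryCatch(solve(A + diag(ridge, m), B), error = function(e) NULL)
      if (!is.null(P) && all(is.finite(P))) break
      ridge <- ridge * 100
    }
  }
  unname(P)
}

#' Orthogonal factor update
#'
#' Updates the c x c factor `F` of the pseudo-label factorization `F Z'`.
#' With `Z` (approximately) column-orthonormal the subproblem reduces to the
#' orthogonal Procrustes problem `min ||W - F|| s.t. F'F = I` with
#' `W = P' X Z`, solved exactly by the polar factor of `W`
#' (`method = "procrustes"`, default). `method = "multiplicative"` instead
#' takes one elementwise step of the rho-penalized stationarity rule, with
#' the signed parts of `W` split across numerator and denominator so a
#' nonnegative-denominator iterate stays well defined.
#'
#' @param P Current m x c projection.
#' @param X Genes x samples matrix.
#' @param Z Current n x c indicator matrix.
#' @param F_current Current c x c factor (used by the multiplicative rule).
#' @param rho Orthogonality penalty constant (multiplicative rule only).
#' @param method `"procrustes"` or `"multiplicative"`.
#' @return Updated c x c matrix; exactly orthogonal under `"procrustes"`.
#' @export
update_F <- function(P, X, Z, F_current, rho = 1e3,
                     method = c("procrustes", "multiplicative")) {
  method <- match.arg(method)
  W <- crossprod(P, X) %*% Z
  if (method == "procrustes") {
    sv <- svd(W)
    if (min(sv$d) < 1e-12 * max(sv$d, 1)) {
      warning("rank-deficient Procrustes target; perturbing", call. = FALSE)
      sv <- svd(W + diag(1e-10, nrow(W)))
    }
    return(sv$u %*% t(sv$v))
  }
  # one step of the penalized elementwise rule; stationarity
  # -W + F + rho (F F'F - F) = 0 split into nonnegative parts
  delta <- 1e-12
  Fc <- F_current
  num <- pmax(W, 0) + rho * Fc
  den <- pmax(-W, 0) + Fc + rho * (Fc %*% crossprod(Fc)) + delta
  Fc * num / den
}

#' Multiplicative indicator update
#'
#' One KKT-derived multiplicative step on the nonnegative relaxed cluster
#' indicator matrix `Z`. The step descends the kappa-penalized subproblem
#' `||P'X - FZ'||^2 + gamma Tr(Z'LZ) + (kappa/4)||Z'Z - I||^2`. The signed
#' parts of `X'PF` and the split `L = D - S` are distributed between
#' numerator and denominator so nonnegativity is preserved:
#' `Z <- Z * ((2 (X'PF)^+ + 2 gamma S Z + kappa Z) /
#'            (2 (X'PF)^- + 2 Z F'F + 2 gamma D Z + kappa Z Z'Z))^(1/2)`.
#' The elementwise square root damps the step: the undamped ratio is
#' scale-unstable around the orthogonality constraint (the quartic `Z Z'Z`
#' term doubles the log-scale error each step, producing a period-2
#' oscillation), while the damped rule has the same fixed points — at a KKT
#' point the ratio is 1 on the support of `Z` — and contracts toward them.
#' This is the standard treatment for multiplicative rules whose
#' denominators contain quartic terms.
#'
#' @param X Genes x samples matrix.
#' @param P Current projection.
#' @param F_mat Current factor.
#' @param Z_current Nonnegative n x c matrix.
#' @param lap [graph_laplacian()] result over the samples.
#' @param gamma Manifold weight.
#' @param kappa Orthogonality penalty constant.
#' @return Updated nonnegative n x c matrix.
#' @export
update_Z <- function(X, P, F_mat, Z_current, lap, gamma = 0, kappa = 1e3) {
  stopifnot(inherits(lap, "graph_laplacian"))
  Z <- as.matrix(Z_current)
  if (any(Z < 0))
    stop("Z must be elementwise nonnegative", call. = FALSE)
  delta <- 1e-12
  XtPF <- crossprod(X, P) %*% F_mat
  S <- lap$D - lap$L
  num <- 2 * pmax(XtPF, 0) + kappa * Z
  den <- 2 * pmax(-XtPF, 0) + 2 * Z %*% crossprod(F_mat) +
    kappa * Z %*% crossprod(Z) + delta
  if (gamma > 0) {
    num <- num + 2 * gamma * (S %*% Z)
    den <- den + 2 * gamma * (lap$D %*% Z)
  }
  unname(Z * sqrt(num / den))
}

#' Objective decomposition
#'
#' Evaluates each term of the selection objective at the current iterate:
#' residual `||P'X - FZ'||_F^2`, sparsity `alpha ||P||_{2,1}` (sum of row
#' l2 norms), redundancy `beta Tr(P' Mbar P)` and manifold
#' `gamma Tr(Z' L Z)`, plus their total.
#'
#' @param X Genes x samples matrix.
#' @param P,F_mat,Z Current iterates.
#' @param adj [adjust_correlation()] result (ignored when `beta = 0`).
#' @param lap [graph_laplacian()] result (ignored when `gamma = 0`).
#' @param alpha,beta,gamma Term weights.
#' @return A list of class `objective_parts` with elements `residual`,
#'   `sparsity`, `correlation`, `manifold`, `total`.
#' @export
objective_parts <- function(X, P, F_mat, Z, adj = NULL, lap = NULL,
                            alpha = 0, beta = 0, gamma = 0) {
  R <- crossprod(P, X) - tcrossprod(F_mat, Z)
  residual <- sum(R^2)
  sparsity <- alpha * sum(sqrt(rowSums(as.matrix(P)^2)))
  correlation <- if (beta > 0) beta * correlation_penalty(P, adj) else 0
  manifold <- if (gamma > 0) gamma * laplacian_quadratic(Z, lap) else 0
  structure(
    list(residual = residual, sparsity = sparsity,
         correlation = correlation, manifold = manifold,
         total = residual + sparsity + correlation + manifold),
    class = "objective_parts")
}

# Run code with a temporary RNG state seeded by `seed`; the caller's RNG
# stream is untouched.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Positive-semidefinite part of a symmetric matrix: eigenvalues clipped at
# zero. Used to keep the covariance penalty convex inside the solver.
psd_part <- function(M) {
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  pos <- pmax(eg$values, 0)
  out <- eg$vectors %*% (pos * t(eg$vectors))
  (out + t(out)) / 2
}

# Spectral initialization of the indicator matrix: k-means on the
# eigenvectors of L belonging to the c smallest eigenvalues, converted to a
# column-normalized nonnegative indicator, then lifted off zero so
# multiplicative updates are never locked. If the similarity graph has no
# edges (a kernel width far below the data's distance scale underflows every
# similarity) the embedding is meaningless; k-means then runs on the top-c
# principal components of the samples instead.
init_Z <- function(X, lap, c, seed) {
  n <- nrow(lap$L)
  if (max(diag(lap$D)) > 1e-8) {
    eg <- eigen(lap$L, symmetric = TRUE)
    emb <- eg$vectors[, seq(n, max(n - c + 1, 1)), drop = FALSE]
  } else {
    emb <- stats::prcomp(t(X), center = TRUE)$x[, seq_len(min(c, n)),
                                                drop = FALSE]
  }
  cl <- with_seed(seed, {
    if (nrow(unique(round(emb, 10))) < c)
      rep_len(seq_len(c), n)               # degenerate embedding
    else
      stats::kmeans(emb, centers = c, nstart = 10, iter.max = 50)$cluster
  })
  Z <- matrix(0, n, c)
  Z[cbind(seq_len(n), cl)] <- 1
  cnt <- pmax(colSums(Z), 1)
  Z <- sweep(Z, 2, sqrt(cnt), "/")
  Z + 0.01
}

#' Fit the gene-selection model
#'
#' Minimizes
#' `||P'X - FZ'||_F^2 + alpha ||P||_{2,1} + beta Tr(P' Mbar P) +
#'  gamma Tr(Z' L Z)` subject to `F'F = I`, `Z'Z ~ I`, `Z >= 0`
#' by alternating block updates: the closed-form reweighted projection
#' update (with a few inner reweighting refinements per sweep), the
#' orthogonal factor update, and the damped multiplicative indicator update
#' (iterated within the sweep until the indicator stops moving, so each
#' sweep is close to an exact block minimization). The adjusted correlation
#' matrix and the sample-graph Laplacian are precomputed once. Iteration
#' stops when the relative objective change drops below `tol` or after
#' `max_iter` sweeps. Deterministic for a fixed `config$seed`.
#'
#' @param data An [expression_dataset()].
#' @param config A [g3cs_config()].
#' @param p_inner Inner reweighting iterations of the P/G pair per sweep
#'   (default 3).
#' @param z_inner Maximum inner multiplicative Z steps per sweep
#'   (default 150); the inner loop stops early once Z is stationary.
#' @return A list of class `g3cs_fit` with elements `P`, `F`, `Z`, `G`,
#'   `objective_trace` (data frame with one row per sweep and columns
#'   `iteration`, `residual`, `sparsity`, `correlation`, `manifold`,
#'   `total`), `iterations`, `converged`, `adj`, `lap`, `config`,
#'   `gene_ids`.
#' @export
#'
#' @examples
#' sim <- generate_dataset(synthetic_spec(n_samples = 30, n_noise = 20,
#'                                        n_informative = 6, n_redundant = 4,
#'                                        seed = 1))
#' fit <- g3cs_fit(sim$data, g3cs_config(n_clusters = 3, seed = 1,
#'                                       max_iter = 30))
#' head(gene_scores(fit$P))
g3cs_fit <- function(data, config, p_inner = 3L, z_inner = 150L) {
  stopifnot(inherits(data, "expression_dataset"),
            inherits(config, "g3cs_config"))
  X <- unname(data$values)
  m <- nrow(X); n <- ncol(X); c <- config$n_clusters
  if (c > min(m, n))
    stop("n_clusters (", c, ") exceeds min(genes, samples) = ", min(m, n),
         call. = FALSE)
  if (config$k_neighbors >= n)
    stop("k_neighbors must be smaller than the number of samples",
         call. = FALSE)

  adj <- if (config$beta > 0) {
    a <- adjust_correlation(covariance_matrix(data),
                            mode = config$correlation_mode)
    if (config$psd_penalty) {
      a$M_bar <- psd_part(a$M_bar)
      a$psd_projected <- TRUE
    }
    a
  } else NULL
  graph <- knn_similarity(data, k = config$k_neighbors, t = config$t_width)
  lap <- graph_laplacian(graph)

  Z <- init_Z(X, lap, c, config$seed)
  F_mat <- diag(c)
  if (config$f_method == "multiplicative") F_mat <- F_mat + 0.01
  alpha <- config$alpha; beta <- config$beta; gamma <- config$gamma

  # sweep-invariant pieces of the P system (X X' + beta Mbar)
  XXt <- tcrossprod(X)
  baseA <- if (beta > 0) XXt + beta * adj$M_bar else XXt
  solve_P <- function(Z, F_mat, g) {
    A <- baseA
    if (alpha > 0) diag(A) <- diag(A) + alpha * g
    B <- X %*% (Z %*% t(F_mat))
    P <- tryCatch(solve(A, B), error = function(e) NULL)
    if (is.null(P) || !all(is.finite(P))) {
      ridge <- 1e-10 * max(mean(abs(diag(A))), 1)
      warning("singular P system; ridge stabilization applied",
              call. = FALSE)
      repeat {
        P <- tryCatch(solve(A + diag(ridge, m), B),
                      error = function(e) NULL)
        if (!is.null(P) && all(is.finite(P))) break
        ridge <- ridge * 100
      }
    }
    P
  }
  Smat <- lap$D - lap$L
  dvec <- diag(lap$D)
  refine_Z <- function(Z, P, F_mat) {
    XtPF <- crossprod(X, P) %*% F_mat
    num0 <- 2 * pmax(XtPF, 0)
    den0 <- 2 * pmax(-XtPF, 0)
    FtF <- crossprod(F_mat)
    for (j in seq_len(z_inner)) {
      num <- num0 + config$kappa * Z
      den <- den0 + 2 * Z %*% FtF + config$kappa * Z %*% crossprod(Z) +
        1e-12
      if (gamma > 0) {
        num <- num + 2 * gamma * (Smat %*% Z)
        den <- den + 2 * gamma * (dvec * Z)
      }
      Zn <- Z * sqrt(num / den)
      moved <- max(abs(Zn - Z)) >= 1e-10 * max(Zn, 1e-300)
      Z <- Zn
      if (!moved) break
    }
    Z
  }

  P <- solve_P(Z, F_mat, rep(0.5, m))  # as if all row norms were 1

  obj <- objective_parts(X, P, F_mat, Z, adj, lap, alpha, beta, gamma)
  prev <- obj$total
  trace <- vector("list", config$max_iter)
  converged <- FALSE
  it <- 0L
  G <- compute_G(P, config$epsilon)  # refreshed each sweep below
  for (it in seq_len(config$max_iter)) {
    g <- NULL
    for (j in seq_len(max(1L, p_inner))) {
      g <- 1 / (2 * pmax(sqrt(rowSums(P^2)), config$epsilon))
      P <- solve_P(Z, F_mat, g)
    }
    G <- diag(g)
    F_mat <- update_F(P, X, Z, F_mat, rho = config$rho,
                      method = config$f_method)
    Z <- refine_Z(Z, P, F_mat)
    obj <- objective_parts(X, P, F_mat, Z, adj, lap, alpha, beta, gamma)
    if (!is.finite(obj$total)) {
      bad <- names(which(!vapply(obj, is.finite, logical(1))))[1L]
      stop("objective became non-finite at sweep ", it,
           " (term: ", bad, ")", call. = FALSE)
    }
    trace[[it]] <- data.frame(iteration = it, residual = obj$residual,
                              sparsity = obj$sparsity,
                              correlation = obj$correlation,
                              manifold = obj$manifold, total = obj$total)
    rel <- abs(obj$total - prev) / max(abs(prev), 1e-12)
    if (rel < config$tol) {
      converged <- TRUE
      break
    }
    prev <- obj$total
  }

  structure(
    list(P = P, F = F_mat, Z = Z, G = G,
         objective_trace = do.call(rbind, trace[seq_len(it)]),
         iterations = it, converged = converged,
         adj = adj, lap = lap, config = config,
         gene_ids = data$gene_ids),
    class = "g3cs_fit")
}

#' @export
print.g3cs_fit <- function(x, ...) {
  cat("g3cs_fit: ", length(x$gene_ids), " genes, ",
      nrow(x$Z), " samples, ", x$config$n_clusters, " clusters\n",
      "  sweeps: ", x$iterations,
      if (x$converged) " (converged)" else " (max_iter reached)", "\n",
      "  final objective: ",
      format(utils::tail(x$objective_trace$total, 1)), "\n", sep = "")
  invisible(x)
}
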