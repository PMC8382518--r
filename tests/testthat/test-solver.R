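test_that("reweighting matrix has the exact entries, floor and homogeneity", {
  G <- compute_G(rbind(c(3, 4), c(0, 0)), epsilon = 1e-8)
  expect_equal(G[1, 1], 0.1)
  expect_equal(G[2, 2], 5e7)
  P <- matrix(rnorm(10), 5, 2)
  expect_equal(diag(compute_G(2 * P, 1e-12)),
               diag(compute_G(P, 1e-12)) / 2, tolerance = 1e-12)
})

test_that("projection update solves its normal equations", {
  # identity design collapses the system to P = Z F'
  c <- 2; n <- 4
  Z <- matrix(runif(n * c), n, c)
  Fm <- random_orthogonal(c)
  P <- update_P(diag(n), Z, Fm, diag(0, n), alpha = 0, beta = 0)
  expect_equal(P, Z %*% t(Fm), tolerance = 1e-10)

  # random instances: explicit residual check of the defining system
  set.seed(71)
  for (r in 1:5) {
    m <- 6; n <- 5
    X <- matrix(rnorm(m * n), m, n)
    Z <- matrix(runif(n * c), n, c)
    Fm <- random_orthogonal(c)
    G <- compute_G(matrix(rnorm(m * c), m, c))
    d <- expression_dataset(X, paste0("g", 1:m), paste0("s", 1:n))
    adj <- adjust_correlation(covariance_matrix(d))
    alpha <- 0.7; beta <- 0.3
    P <- update_P(X, Z, Fm, G, adj, alpha, beta)
    lhs <- (tcrossprod(X) + alpha * G + beta * adj$M_bar) %*% P
    rhs <- X %*% Z %*% t(Fm)
    expect_lt(norm(lhs - rhs, "F") / max(norm(rhs, "F"), 1e-12), 1e-8)
  }
})

test_that("large ridge-like correlation weight shrinks the projection", {
  set.seed(72)
  X <- matrix(rnorm(30), 6, 5)
  Z <- matrix(runif(10), 5, 2)
  Fm <- diag(2)
  G <- diag(0.5, 6)
  adjI <- structure(list(M_bar = diag(6), mode = "printed",
                         symmetrized = TRUE),
                    class = "adjusted_correlation")
  norms <- sapply(c(1, 10, 100, 1000), function(b)
    norm(update_P(X, Z, Fm, G, adjI, alpha = 0, beta = b), "F"))
  expect_true(all(diff(norms) < 0))
})

test_that("Procrustes factor update is exact", {
  # an already-orthogonal target is a fixed point, with zero stationarity
  Fm <- random_orthogonal(3)
  # craft X, P, Z so that W = P'XZ equals Fm: X = I, P = Fm', Z = I
  out <- update_F(t(Fm), diag(3), diag(3), diag(3))
  expect_equal(out, Fm, tolerance = 1e-10)
  rho <- 7
  stat <- -Fm + out + rho * (out %*% crossprod(out) - out)
  expect_lt(max(abs(stat)), 1e-10)

  # positive diagonal target -> identity
  expect_equal(update_F(diag(c(2, 0.5)), diag(2), diag(2), diag(2)),
               diag(2), tolerance = 1e-12)

  # signed off-diagonal target -> its polar factor
  W <- rbind(c(0, -3), c(2, 0))
  expect_equal(update_F(t(W), diag(2), diag(2), diag(2)),
               rbind(c(0, -1), c(1, 0)), tolerance = 1e-12)
})

test_that("Procrustes beats random orthogonal candidates", {
  set.seed(81)
  for (r in 1:5) {
    W <- matrix(rnorm(9), 3, 3)
    Fhat <- update_F(t(W), diag(3), diag(3), diag(3))
    best <- norm(W - Fhat, "F")
    cand <- replicate(200, norm(W - random_orthogonal(3), "F"))
    expect_true(all(best <= cand + 1e-12))
  }
})

test_that("multiplicative factor rule fixes stationary points and stays finite", {
  # at a positive orthogonal-ish fixed point the rule does not move
  Fm <- diag(2) * 0.6 + 0.4      # positive entries
  rho <- 5
  W <- Fm + rho * (Fm %*% crossprod(Fm) - Fm)  # makes stationarity exact
  out <- update_F(t(W), diag(2), diag(2), Fm, rho = rho,
                  method = "multiplicative")
  expect_equal(out, Fm, tolerance = 1e-6)
  expect_true(all(is.finite(
    update_F(rbind(c(0, 2), c(-3, 0)), diag(2), diag(2),
             matrix(0.5, 2, 2), rho = 10, method = "multiplicative"))))
})

test_that("indicator update preserves nonnegativity and fixed points", {
  set.seed(91)
  n <- 6; c <- 2
  X <- matrix(rnorm(5 * n), 5, n)
  P <- matrix(rnorm(5 * c), 5, c)
  Fm <- random_orthogonal(c)
  S <- matrix(runif(n * n), n, n); S <- (S + t(S)) / 2; diag(S) <- 0
  lap <- graph_laplacian(as_similarity_graph(S))
  Z <- matrix(runif(n * c) + 0.1, n, c)
  Zn <- update_Z(X, P, Fm, Z, lap, gamma = 0.5, kappa = 10)
  expect_true(all(Zn >= 0))
  expect_error(update_Z(X, P, Fm, Z - 1, lap), "nonnegative")

  # penalty-dominated limit: a nonnegative column-orthonormal Z (disjoint
  # supports) is fixed to first order
  Zo <- matrix(0, n, c)
  Zo[cbind(seq_len(n), rep_len(seq_len(c), n))] <- runif(n) + 0.5
  Zo <- sweep(Zo, 2, sqrt(colSums(Zo^2)), "/")
  Zbig <- update_Z(X, P, Fm, Zo, lap, gamma = 0.5, kappa = 1e12)
  expect_equal(Zbig, Zo, tolerance = 1e-6)
})

test_that("indicator update descends its penalized subproblem", {
  # the kappa-penalized Lagrangian of the Z subproblem does not increase
  penalized <- function(Z, X, P, Fm, lap, gamma, kappa) {
    R <- crossprod(P, X) - tcrossprod(Fm, Z)
    sum(R^2) + gamma * laplacian_quadratic(Z, lap) +
      (kappa / 4) * norm(crossprod(Z) - diag(ncol(Z)), "F")^2
  }
  set.seed(92)
  for (r in 1:5) {
    n <- 6; c <- 2
    X <- matrix(rnorm(4 * n), 4, n)
    P <- matrix(rnorm(4 * c), 4, c)
    Fm <- random_orthogonal(c)
    S <- matrix(runif(n * n), n, n); S <- (S + t(S)) / 2; diag(S) <- 0
    lap <- graph_laplacian(as_similarity_graph(S))
    Z <- matrix(runif(n * c) + 0.05, n, c)
    gamma <- 0.5; kappa <- 50
    before <- penalized(Z, X, P, Fm, lap, gamma, kappa)
    for (j in 1:50)
      Z <- update_Z(X, P, Fm, Z, lap, gamma = gamma, kappa = kappa)
    after <- penalized(Z, X, P, Fm, lap, gamma, kappa)
    expect_lte(after, before + 1e-9 * abs(before))
  }
})

test_that("objective decomposition matches an independent re-evaluation", {
  # zero-residual, zero-weight configuration gives total 0
  X <- diag(3)
  Z <- diag(3); Fm <- diag(3); P <- Z %*% t(Fm)
  ob <- objective_parts(X, P, Fm, Z)
  expect_equal(ob$total, 0)

  # row-norm sum by hand
  ob2 <- objective_parts(diag(2), rbind(c(3, 4), c(0, 0)), diag(2),
                         rbind(c(3, 0), c(4, 0)), alpha = 1)
  expect_equal(ob2$sparsity, 5)

  # random instance against a single-expression oracle
  set.seed(93)
  m <- 7; n <- 6; c <- 2
  X <- matrix(rnorm(m * n), m, n)
  P <- matrix(rnorm(m * c), m, c)
  Fm <- random_orthogonal(c)
  Z <- matrix(runif(n * c), n, c)
  d <- expression_dataset(X, paste0("g", 1:m), paste0("s", 1:n))
  adj <- adjust_correlation(covariance_matrix(d))
  S <- matrix(runif(n * n), n, n); S <- (S + t(S)) / 2; diag(S) <- 0
  lap <- graph_laplacian(as_similarity_graph(S))
  a <- 0.3; b <- 0.7; g <- 1.1
  ob3 <- objective_parts(X, P, Fm, Z, adj, lap, a, b, g)
  oracle <- norm(t(P) %*% X - Fm %*% t(Z), "F")^2 +
    a * sum(sqrt(rowSums(P^2))) +
    b * sum(diag(t(P) %*% adj$M_bar %*% P)) +
    g * sum(diag(t(Z) %*% lap$L %*% Z))
  expect_equal(ob3$total, oracle, tolerance = 1e-12)
  expect_equal(ob3$total,
               ob3$residual + ob3$sparsity + ob3$correlation + ob3$manifold)
})

test_that("reweighted l2,1 iteration alone is monotone", {
  set.seed(94)
  m <- 12; n <- 8; c <- 2
  X <- matrix(rnorm(m * n), m, n)
  Z <- qr.Q(qr(matrix(runif(n * c), n, c)))
  Fm <- random_orthogonal(c)
  d <- expression_dataset(X, paste0("g", 1:m), paste0("s", 1:n))
  adj <- adjust_correlation(covariance_matrix(d))
  adj$M_bar <- g3cs:::psd_part(adj$M_bar)   # convex penalty form
  alpha <- 0.5; beta <- 0.2
  objP <- function(P) {
    norm(t(P) %*% X - Fm %*% t(Z), "F")^2 +
      alpha * sum(sqrt(rowSums(P^2))) + beta * correlation_penalty(P, adj)
  }
  P <- update_P(X, Z, Fm, diag(0.5, m), adj, alpha, beta)
  vals <- objP(P)
  for (j in 1:25) {
    P <- update_P(X, Z, Fm, compute_G(P, 1e-8), adj, alpha, beta)
    vals <- c(vals, objP(P))
  }
  expect_true(all(diff(vals) <= 1e-9 * pmax(abs(vals[-length(vals)]), 1)))
})

test_that("fit is deterministic and stops by the rules", {
  sim <- generate_dataset(synthetic_spec(n_samples = 30, n_clusters = 3,
                                         n_informative = 6, n_redundant = 6,
                                         n_noise = 30, seed = 5))
  cfg <- g3cs_config(n_clusters = 3, seed = 5, max_iter = 40)
  f1 <- g3cs_fit(sim$data, cfg)
  f2 <- g3cs_fit(sim$data, cfg)
  expect_identical(f1$objective_trace, f2$objective_trace)
  expect_identical(f1$P, f2$P)

  # infinite tolerance: exactly one sweep, flagged converged
  cfg_inf <- g3cs_config(n_clusters = 3, seed = 5, tol = Inf)
  f3 <- g3cs_fit(sim$data, cfg_inf)
  expect_equal(f3$iterations, 1L)
  expect_true(f3$converged)

  expect_error(
    g3cs_fit(sim$data, g3cs_config(n_clusters = 31, seed = 1)),
    "n_clusters")
})
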