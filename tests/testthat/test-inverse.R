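# Regularized minimum-norm inversion and L-curve selection.

test_that("identity system gives the closed-form shrinkage operator", {
  op <- make_inverse_operator(diag(2), NULL, diag(2), 1)
  expect_equal(op$w, diag(2) / 2, tolerance = 1e-12)
  expect_equal(apply_inverse(op, matrix(c(2, 4))), matrix(c(1, 2)),
               tolerance = 1e-12)
})

test_that("the unregularized limit inverts a well-conditioned square system", {
  set.seed(1)
  L <- diag(4) + 0.2 * matrix(stats::rnorm(16), 4)
  S <- matrix(stats::rnorm(4 * 30), 4)
  op <- make_inverse_operator(L, NULL, diag(4), 0)
  expect_lt(rel_diff(apply_inverse(op, L %*% S), S), 1e-6)
  # and nearly-zero regularization is consistent too
  op2 <- make_inverse_operator(L, NULL, diag(4), 1e-12)
  expect_lt(rel_diff(apply_inverse(op2, L %*% S), S), 1e-6)
  expect_true(all(apply_inverse(op, matrix(0, 4, 5)) == 0))
})

test_that("operator equals the ridge normal-equation oracle", {
  set.seed(2)
  L <- matrix(stats::rnorm(5 * 8), 5, 8)
  op <- make_inverse_operator(L, NULL, diag(5), 0.1)
  oracle <- t(L) %*% solve(L %*% t(L) + 0.1 * diag(5))
  expect_lt(rel_diff(op$w, oracle), 1e-10)
})

test_that("operator minimizes the penalized least-squares objective", {
  # independent oracle: the normal equations of the explicit objective
  # ||Q^{-1/2}(M - L S)||^2 + g ||R^{-1/2} S||^2, i.e.
  # S* = (L' Qi L + g Ri)^{-1} L' Qi M  -- a different algebraic route
  # than the covariance form R L'(L R L' + g Q)^{-1} M
  set.seed(3)
  for (i in 1:20) {
    n_ch <- sample(3:6, 1)
    n_src <- sample(4:9, 1)
    L <- matrix(stats::rnorm(n_ch * n_src), n_ch)
    A <- matrix(stats::rnorm(n_ch^2), n_ch)
    Q <- crossprod(A) + diag(n_ch)
    B <- matrix(stats::rnorm(n_src^2), n_src)
    R <- crossprod(B) + diag(n_src)
    g <- 10^stats::runif(1, -3, 1)
    M <- matrix(stats::rnorm(n_ch * 7), n_ch)

    op <- make_inverse_operator(L, R, Q, g)
    S_hat <- apply_inverse(op, M)
    Qi <- solve(Q); Ri <- solve(R)
    S_star <- solve(t(L) %*% Qi %*% L + g * Ri, t(L) %*% Qi %*% M)
    expect_lt(rel_diff(S_hat, S_star), 1e-8)
  }
})

test_that("prewhitened coordinates give the same estimate", {
  set.seed(4)
  L <- matrix(stats::rnorm(6 * 15), 6)
  A <- matrix(stats::rnorm(36), 6)
  Q <- crossprod(A) + diag(6)
  M <- matrix(stats::rnorm(6 * 10), 6)
  g <- 0.3
  S1 <- apply_inverse(make_inverse_operator(L, NULL, Q, g), M)
  # whiten: Qw^{-1/2} applied to both L and M, then Q = I
  e <- eigen(Q, symmetric = TRUE)
  Qmh <- e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)
  S2 <- apply_inverse(make_inverse_operator(Qmh %*% L, NULL, diag(6), g),
                      Qmh %*% M)
  expect_lt(rel_diff(S1, S2), 1e-8)
})

test_that("solutions shrink monotonically with the regularization weight", {
  set.seed(5)
  L <- matrix(stats::rnorm(8 * 20), 8)
  M <- matrix(stats::rnorm(8 * 40), 8)
  weights <- 10^seq(-4, 4, by = 1)
  norms <- vapply(weights, function(g) {
    sqrt(sum(apply_inverse(make_inverse_operator(L, NULL, diag(8), g),
                           M)^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-9 * norms[-length(norms)]))
  # operator norm itself vanishes as the weight grows without bound
  w1 <- make_inverse_operator(L, NULL, diag(8), 1)$w
  w2 <- make_inverse_operator(L, NULL, diag(8), 1e6)$w
  expect_lt(sqrt(sum(w2^2)), sqrt(sum(w1^2)))
})

test_that("singular unregularized systems are rejected with advice", {
  L <- matrix(1, 3, 5)  # rank 1
  expect_error(make_inverse_operator(L, NULL, diag(3), 0),
               "rank-deficient")
  expect_error(make_inverse_operator(matrix(1:6, 2), NULL, diag(2), -1),
               "nonnegative")
  expect_error(apply_inverse(make_inverse_operator(diag(2), NULL, diag(2), 1),
                             matrix(0, 3, 4)),
               "shape error")
})

test_that("lambda_grid spans decades inclusively", {
  expect_equal(lambda_grid(-11, -5),
               c(1e-11, 1e-10, 1e-9, 1e-8, 1e-7, 1e-6, 1e-5))
  expect_equal(length(lambda_grid(-11, -5)), 7)
  expect_equal(lambda_grid(-3, -3), 1e-3)
  expect_equal(lambda_grid(-2, -1), c(1e-2, 1e-1))
  expect_error(lambda_grid(-1, -2))
})

test_that("L-curve norms are monotone and the corner lands on the bend", {
  # diagonal system with singular values {10, 1, 0.01}: components above
  # the noise floor are recovered until the weight crosses s^2, so the
  # curvature concentrates near the smallest informative s^2 ~ 1e-2
  sv <- c(10, 1, 0.01)
  L <- diag(sv)
  set.seed(8)
  S <- matrix(stats::rnorm(3 * 400), 3)
  M <- L %*% S + 0.05 * matrix(stats::rnorm(3 * 400), 3)
  grid <- 10^seq(-6, 4, by = 1)
  lc <- lcurve_select(L, NULL, diag(3), M, grid)
  expect_true(all(diff(lc$residual_norms) >= -1e-9 * lc$residual_norms[-1]))
  expect_true(all(diff(lc$solution_norms) <= 1e-9 * lc$solution_norms[-1]))

  # oracle: brute-force curvature on a dense grid via the SVD shrinkage
  # closed form (independent of the package's solve-based path)
  dense <- 10^seq(-6, 4, by = 0.1)
  res_o <- sol_o <- numeric(length(dense))
  for (i in seq_along(dense)) {
    g <- dense[i]
    shrink <- sv / (sv^2 + g)          # W = diag(shrink)
    S_hat <- diag(shrink) %*% M
    res_o[i] <- sqrt(sum((M - L %*% S_hat)^2))
    sol_o[i] <- sqrt(sum(S_hat^2))
  }
  lx <- log10(res_o); ly <- log10(sol_o)
  curv <- rep(NA_real_, length(dense))
  for (i in 2:(length(dense) - 1)) {
    a <- c(lx[i] - lx[i - 1], ly[i] - ly[i - 1])
    b <- c(lx[i + 1] - lx[i], ly[i + 1] - ly[i])
    cr <- abs(a[1] * b[2] - a[2] * b[1])
    d1 <- sqrt(sum(a^2)); d2 <- sqrt(sum(b^2))
    d3 <- sqrt(sum((a + b)^2))
    curv[i] <- if (d1 * d2 * d3 > 0) 2 * cr / (d1 * d2 * d3) else 0
  }
  corner_oracle <- dense[which.max(curv)]
  expect_lt(abs(log10(lc$corner_weight) - log10(corner_oracle)), 1)
})

test_that("degenerate L-curves are rejected", {
  L <- diag(3)
  M <- matrix(stats::rnorm(3 * 50), 3)
  expect_error(lcurve_select(L, NULL, diag(3), M, c(1e-3, 1e-2)),
               "at least 3")
})
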