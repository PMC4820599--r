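# Tikhonov-regularized minimum-norm inversion and L-curve selection.

#' Build a regularized minimum-norm inverse operator
#'
#' Computes `W = R L' (L R L' + reg_weight * Q)^{-1}` through a symmetric
#' linear solve (never an explicit inverse).  `R` is the source covariance
#' (identity for the classical MNE, the default) and `Q` the noise
#' covariance; `reg_weight` is the composite Tikhonov weight multiplying
#' `Q` in the solved system.  `Q` is ridge-stabilized by
#' `1e-12 * tr(Q)/n_channels` on its diagonal so that covariances estimated
#' from short noise segments remain usable.
#'
#' @param lf a `lead_field` or bare channels x sources gain matrix.
#' @param source_cov source covariance `R` (matrix) or `NULL` for identity.
#' @param noise_cov a `noise_covariance`, or a bare symmetric PSD matrix.
#' @param reg_weight nonnegative regularization weight.
#' @return An object of class `inverse_operator` with `w` (sources x
#'   channels), `reg_weight`, `source_cov` (`NULL` = identity), `noise_cov`.
#' @export
make_inverse_operator <- function(lf, source_cov = NULL, noise_cov,
                                  reg_weight) {
  L <- if (inherits(lf, "lead_field")) lf$gain else as.matrix(lf)
  Q <- if (inherits(noise_cov, "noise_covariance")) noise_cov$q
       else as.matrix(noise_cov)
  if (reg_weight < 0) stop("reg_weight must be nonnegative")
  if (nrow(Q) != nrow(L) || ncol(Q) != nrow(L))
    stop("noise covariance must be channels x channels")
  if (max(abs(Q - t(Q))) > 1e-8 * max(abs(Q), 1e-300))
    stop("noise covariance must be symmetric")
  Qs <- stabilize_cov(Q)
  LR <- if (is.null(source_cov)) L else L %*% source_cov
  A <- tcrossprod(LR, L) + reg_weight * Qs
  A <- (A + t(A)) / 2
  B <- tryCatch(solve(A, L),
                error = function(e)
                  stop("rank-deficient system at reg_weight = ", reg_weight,
                       "; increase the regularization weight", call. = FALSE))
  w <- if (is.null(source_cov)) t(B) else source_cov %*% t(B)
  structure(list(w = w, reg_weight = reg_weight, source_cov = source_cov,
                 noise_cov = Qs),
            class = "inverse_operator")
}

stabilize_cov <- function(Q) {
  Q + diag(1e-12 * sum(diag(Q)) / nrow(Q), nrow(Q))
}

#' @export
print.inverse_operator <- function(x, ...) {
  cat(sprintf("inverse_operator: %d sources x %d channels, reg_weight %.3g\n",
              nrow(x$w), ncol(x$w), x$reg_weight))
  invisible(x)
}

#' Apply an inverse operator to sensor data
#'
#' @param op an `inverse_operator`.
#' @param sensor_data channels x time matrix.
#' @return sources x time matrix of estimated source activity.
#' @export
apply_inverse <- function(op, sensor_data) {
  sensor_data <- as.matrix(sensor_data)
  if (ncol(op$w) != nrow(sensor_data))
    stop("shape error: operator expects ", ncol(op$w), " channels, data has ",
         nrow(sensor_data))
  op$w %*% sensor_data
}

#' Decade grid of regularization weights
#'
#' @param low_exponent,high_exponent integer exponents; the grid is
#'   `10^low, ..., 10^high` in unit-decade steps.
#' @return Numeric vector of weights.
#' @examples
#' lambda_grid(-11, -5)  # the study's 7-value grid
#' @export
lambda_grid <- function(low_exponent, high_exponent) {
  stopifnot(low_exponent <= high_exponent)
  10^seq(low_exponent, high_exponent, by = 1)
}

#' L-curve over a grid of regularization weights
#'
#' For each weight, solves the minimum-norm problem and records the
#' whitened residual norm `||Q^{-1/2}(M - L S_hat)||_F` and the weighted
#' solution norm `||R^{-1/2} S_hat||_F`.  The corner is the interior grid
#' point of maximum discrete curvature of the `(log10 residual, log10
#' solution)` polyline, measured by the circumscribed-circle curvature of
#' each consecutive point triple.  Both norms are computed from the data's
#' second-moment matrix, so the cost is independent of the series length.
#'
#' @param lf a `lead_field` or gain matrix.
#' @param source_cov source covariance or `NULL` for identity.
#' @param noise_cov noise covariance (`noise_covariance` or matrix).
#' @param sensor_data channels x time matrix.
#' @param grid numeric vector of at least 3 regularization weights.
#' @return An object of class `lcurve`: `grid`, `residual_norms`,
#'   `solution_norms`, `curvatures` (NA at the endpoints), `corner_weight`,
#'   `corner_index`.
#' @export
lcurve_select <- function(lf, source_cov = NULL, noise_cov, sensor_data,
                          grid) {
  if (length(grid) < 3)
    stop("corner undefined: the L-curve needs a grid of at least 3 weights")
  grid <- sort(grid)
  L <- if (inherits(lf, "lead_field")) lf$gain else as.matrix(lf)
  Q <- if (inherits(noise_cov, "noise_covariance")) noise_cov$q
       else as.matrix(noise_cov)
  Qs <- stabilize_cov(Q)
  Qi <- solve(Qs)
  C <- tcrossprod(as.matrix(sensor_data))  # M M', channels x channels
  Ri <- if (is.null(source_cov)) NULL else solve(source_cov)

  res <- sol <- numeric(length(grid))
  for (i in seq_along(grid)) {
    op <- make_inverse_operator(L, source_cov, Qs, grid[i])
    W <- op$w
    E <- diag(nrow(L)) - L %*% W          # residual projector
    # ||Q^{-1/2} E M||_F^2 = tr(Qi E C E')
    res[i] <- sqrt(max(0, sum(Qi * (E %*% C %*% t(E)))))
    # ||R^{-1/2} W M||_F^2 = tr(Ri W C W')
    WC <- W %*% C
    sol[i] <- if (is.null(Ri)) sqrt(max(0, sum(WC * W)))
              else sqrt(max(0, sum((Ri %*% WC) * W)))
  }

  lx <- log10(pmax(res, 1e-300))
  ly <- log10(pmax(sol, 1e-300))
  curv <- rep(NA_real_, length(grid))
  for (i in 2:(length(grid) - 1)) {
    curv[i] <- circumcircle_curvature(lx[i - 1], ly[i - 1], lx[i], ly[i],
                                      lx[i + 1], ly[i + 1])
  }
  if (all(!is.finite(curv) | curv <= 1e-10, na.rm = TRUE))
    stop("corner undefined: L-curve is collinear in log-log; ",
         "widen the regularization grid")
  idx <- which.max(ifelse(is.na(curv), -Inf, curv))
  structure(list(grid = grid, residual_norms = res, solution_norms = sol,
                 curvatures = curv, corner_weight = grid[idx],
                 corner_index = idx),
            class = "lcurve")
}

# curvature (1/radius) of the circle through three points; 0 if collinear
circumcircle_curvature <- function(x1, y1, x2, y2, x3, y3) {
  a <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  b <- sqrt((x3 - x2)^2 + (y3 - y2)^2)
  c <- sqrt((x3 - x1)^2 + (y3 - y1)^2)
  cross <- (x2 - x1) * (y3 - y1) - (y2 - y1) * (x3 - x1)
  area2 <- abs(cross)
  if (a * b * c == 0) return(0)
  2 * area2 / (a * b * c)
}

#' @export
print.lcurve <- function(x, ...) {
  cat(sprintf("lcurve: %d weights, corner at %.3g\n",
              length(x$grid), x$corner_weight))
  invisible(x)
}
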