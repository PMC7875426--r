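#' Elastic-net fit of a lagged design
#'
#' Minimizes the penalized least-squares objective
#' \deqn{\|y - X\beta\|_2^2 + \lambda\,(a\|\beta\|_1 + (1-a)\|\beta\|_2^2)}
#' by cyclic coordinate descent on the Gram matrix, with no intercept (the
#' data are centered upstream).  Note the penalty is exactly as written:
#' there is no 1/2 on the quadratic term and no 1/n on the loss, so `a = 0`
#' is ridge with closed form \eqn{(X'X + \lambda I)^{-1} X'y} and `a = 1`
#' on an orthonormal design soft-thresholds the OLS coefficients at
#' \eqn{\lambda / 2}.
#'
#' @param design a [build_design()] object, or a numeric predictor matrix.
#' @param y response vector (ignored when `design` is a `lagged_design`).
#' @param lambda penalty strength, positive.
#' @param a mixing weight in `[0, 1]` (1 = lasso, 0 = ridge).
#' @param tol,maxit coordinate-descent convergence controls.
#' @return Numeric coefficient vector, one entry per design column.
#' @export
enet_fit <- function(design, lambda, a, y = NULL, tol = 1e-12, maxit = 100000L) {
  if (inherits(design, "lagged_design")) {
    X <- design$predictors
    y <- design$response
  } else X <- design
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop_("non-finite entries in the design")
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0)
    stop_("lambda must be a single non-negative number")
  check_scalar_prob(a, "a", open = FALSE)
  b <- .cd_enet_gram(crossprod(X), crossprod(X, y)[, 1], lambda, a,
                     numeric(ncol(X)), tol, as.integer(maxit))
  names(b) <- colnames(X)
  b
}

# Gram-scale grid solve used by the LOOCV and bootstrap loops.  `grid` is a
# data frame with columns lambda, a ordered so that warm starts are useful
# (a-major, lambda decreasing within a).
enet_fit_gram_grid <- function(G, xty, grid, tol = 1e-12, maxit = 100000L) {
  .cd_enet_gram_grid(G, xty, grid$lambda, grid$a, tol, as.integer(maxit))
}

default_lambda_grid <- function() 10^seq(-4, 0)
default_a_grid <- function() seq(0.1, 0.9, by = 0.2)

make_penalty_grid <- function(lambda_grid, a_grid) {
  if (!length(lambda_grid) || any(lambda_grid <= 0))
    stop_("lambda_grid must be positive and non-empty")
  if (!length(a_grid) || any(a_grid < 0 | a_grid > 1))
    stop_("a_grid entries must lie in [0, 1]")
  # a-major, lambda decreasing within each a: good warm starts
  data.frame(
    lambda = rep(sort(lambda_grid, decreasing = TRUE), times = length(a_grid)),
    a = rep(sort(a_grid), each = length(lambda_grid))
  )
}

#' Select penalty hyperparameters by leave-one-out cross-validation
#'
#' For every grid point \eqn{(\lambda, a)}, every gene and every design row
#' `i`, the model is refit on the remaining rows and the squared prediction
#' error on row `i` is accumulated, scaled by `1/N` per gene; the grid point
#' with the smallest total error over all genes and rows is returned.  One
#' pair is shared by all genes.  Ties are broken toward the sparser model:
#' larger `lambda` first, then larger `a`.
#'
#' @param designs list of [build_design()] objects, one per effect gene.
#' @param lambda_grid,a_grid candidate penalty strengths and mixing weights.
#' @return A list with `lambda`, `a`, and `mse` (matrix of cross-validation
#'   errors, lambdas in rows, a values in columns).
#' @export
loocv_select <- function(designs,
                         lambda_grid = default_lambda_grid(),
                         a_grid = default_a_grid()) {
  grid <- make_penalty_grid(lambda_grid, a_grid)
  err <- numeric(nrow(grid))
  for (d in designs) {
    X <- d$predictors; y <- d$response
    N <- d$N
    if (N < 2L) stop_("LOOCV needs at least two design rows")
    G <- crossprod(X)
    xty <- crossprod(X, y)[, 1]
    for (i in seq_len(N)) {
      xi <- X[i, ]
      Gi <- G - tcrossprod(xi)
      xtyi <- xty - xi * y[i]
      B <- enet_fit_gram_grid(Gi, xtyi, grid)
      pred <- drop(xi %*% B)
      err <- err + (y[i] - pred)^2 / N
    }
  }
  if (!any(is.finite(err))) stop_("all grid points gave non-finite error")
  # smallest error; ties -> larger lambda, then larger a
  ord <- order(err, -grid$lambda, -grid$a)
  best <- ord[1]
  mse <- matrix(NA_real_, length(lambda_grid), length(a_grid),
                dimnames = list(format(sort(lambda_grid, decreasing = TRUE)),
                                format(sort(a_grid))))
  mse[cbind(match(grid$lambda, sort(lambda_grid, decreasing = TRUE)),
            match(grid$a, sort(a_grid)))] <- err
  list(lambda = grid$lambda[best], a = grid$a[best], mse = mse)
}

# Hybrid series realizing the permutation null for one effect gene: the
# effect gene keeps its original (unpermuted) profile while every other
# gene's profile is taken from the permuted series.
null_hybrid_ts <- function(ts, permuted, effect_gene) {
  if (!identical(genes.expression_ts(ts), genes.expression_ts(permuted)))
    stop_("gene sets of the original and permuted series differ")
  g <- match(effect_gene, genes.expression_ts(ts))
  permuted$values[g, , ] <- ts$values[g, , ]
  permuted
}

#' Fit null (permutation) coefficients for one effect gene
#'
#' Regresses the effect gene's unpermuted expression on its own unpermuted
#' lagged values together with the permuted lagged values of all other
#' genes, at the same penalty as the real fit.  The resulting cross-gene
#' coefficients form the null distribution used for edge-FDR calibration.
#'
#' @param ts original complete, centered series.
#' @param permuted output of [permute_profiles()] on `ts`.
#' @param effect_gene gene label.
#' @param lambda,a penalty selected on the original data.
#' @param lag maximum lag.
#' @return Coefficient vector in design column order.
#' @export
fit_null_coefficients <- function(ts, permuted, effect_gene, lambda, a, lag = 2) {
  d <- build_design(null_hybrid_ts(ts, permuted, effect_gene), effect_gene, lag)
  enet_fit(d, lambda, a)
}
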