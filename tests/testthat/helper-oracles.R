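# Independent reference implementations used as oracles.  These deliberately
# avoid the package's code paths: closed forms, proximal gradient, and naive
# enumerations.

ridge_closed_form <- function(X, y, lambda) {
  as.numeric(solve(crossprod(X) + lambda * diag(ncol(X)), crossprod(X, y)))
}

soft_threshold <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

# Proximal gradient (ISTA) minimizer of ||y - Xb||^2 + lambda(a|b|_1 + (1-a)|b|_2^2),
# an algorithm family independent of coordinate descent.
ista_enet <- function(X, y, lambda, a, iters = 200000, tol = 1e-13) {
  G <- crossprod(X)
  xty <- crossprod(X, y)[, 1]
  step <- 1 / (2 * (max(eigen(G, only.values = TRUE)$values) + lambda * (1 - a)))
  b <- numeric(ncol(X))
  for (i in seq_len(iters)) {
    grad <- 2 * (G %*% b - xty) + 2 * lambda * (1 - a) * b
    bn <- soft_threshold(b - step * grad[, 1], step * lambda * a)
    if (max(abs(bn - b)) < tol) return(bn)
    b <- bn
  }
  b
}

enet_objective <- function(X, y, b, lambda, a) {
  sum((y - X %*% b)^2) + lambda * (a * sum(abs(b)) + (1 - a) * sum(b^2))
}

# Average precision by direct enumeration over an explicit ordering of
# labels (TRUE = relevant).
ap_enumeration <- function(truth_in_order) {
  hits <- which(truth_in_order)
  mean(vapply(seq_along(hits), function(k) k / hits[k], 0))
}

# A tiny deterministic series: values[g, t, r] laid out explicitly.
tiny_ts <- function(values, times = NULL) {
  expression_ts(values, times = times)
}

# Random complete centered series for property loops.
random_ts <- function(p, Tn, R, seed) {
  set.seed(seed)
  center_profiles(expression_ts(array(rnorm(p * Tn * R), c(p, Tn, R))))
}

expect_silent_file <- function(path) {
  expect_true(file.exists(path))
}
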