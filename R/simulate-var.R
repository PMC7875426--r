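#' Simulate replicated time series from a sparse planted VAR network
#'
#' Generates a random sparse lagged coefficient structure (the planted
#' network), rescales it if necessary so the companion-form spectral radius
#' is at most 0.95 (stationarity), then iterates the vector autoregression
#' with Gaussian innovations from a 200-step burn-in for each replicate.
#' The defaults emulate a DREAM-style benchmark shape scaled to desk size:
#' 15 genes, edge density 0.05, 21 time points and 10 replicates, with
#' moderate innovation noise.
#'
#' Each planted cross-gene edge receives a coefficient drawn uniformly from
#' `coefficient_range` at a single uniformly chosen lag, negated with
#' probability `sign_mix`; every gene also gets a lag-1 autoregressive
#' coefficient drawn from `self_decay`.
#'
#' @param p number of genes.
#' @param density probability of a directed edge between an ordered gene
#'   pair.
#' @param lag maximum lag of the generating process.
#' @param n_times,n_reps time points and replicates to record.
#' @param coefficient_range range of planted edge magnitudes.
#' @param sign_mix probability that a planted edge is negative.
#' @param self_decay range of lag-1 autoregressive coefficients.
#' @param noise_sd innovation standard deviation.
#' @param seed integer seed.
#' @param burn_in burn-in steps before recording.
#' @return A list with `ts` (an [expression_ts()]), `gold` (a
#'   [gold_standard()] of the planted directed edges), and `coefficients`
#'   (the `p x p x L` cause-by-effect-by-lag array actually used, self
#'   coefficients on the diagonal).
#' @export
simulate_var <- function(p = 15, density = 0.05, lag = 2,
                         n_times = 21, n_reps = 10,
                         coefficient_range = c(0.5, 1),
                         sign_mix = 0.3,
                         self_decay = c(0.2, 0.5),
                         noise_sd = 0.2,
                         seed = 1,
                         burn_in = 200) {
  check_scalar_prob(density, "density", open = FALSE)
  check_scalar_prob(sign_mix, "sign_mix", open = FALSE)
  if (n_times < lag + 1) stop_("need n_times >= lag + 1")
  genes <- sprintf("g%d", seq_len(p))
  with_seed(seed, {
    coefs <- array(0, c(p, p, lag), dimnames = list(genes, genes, NULL))
    is_edge <- matrix(runif(p * p) < density, p, p)
    diag(is_edge) <- FALSE
    for (i in which(is_edge)) {
      cause <- (i - 1) %% p + 1
      effect <- (i - 1) %/% p + 1
      mag <- runif(1, coefficient_range[1], coefficient_range[2])
      sgn <- if (runif(1) < sign_mix) -1 else 1
      coefs[cause, effect, sample.int(lag, 1)] <- sgn * mag
    }
    for (g in seq_len(p)) coefs[g, g, 1] <- runif(1, self_decay[1], self_decay[2])
    coefs <- enforce_stationarity(coefs)
    vals <- array(0, c(p, n_times, n_reps))
    for (r in seq_len(n_reps)) {
      vals[, , r] <- iterate_var(coefs, n_times, noise_sd, burn_in)
    }
  })
  gold_edges <- which(apply(coefs != 0, c(1, 2), any) &
                        !diag(TRUE, p), arr.ind = TRUE)
  gold <- gold_standard(
    data.frame(cause = genes[gold_edges[, 1]], effect = genes[gold_edges[, 2]],
               stringsAsFactors = FALSE),
    universe = genes
  )
  list(ts = expression_ts(vals, genes = genes), gold = gold, coefficients = coefs)
}

# Shrink the coefficient array until the companion-form spectral radius is
# at most 0.95; errors if 100 shrink steps do not suffice.
enforce_stationarity <- function(coefs) {
  p <- dim(coefs)[1]; L <- dim(coefs)[3]
  radius <- function(cf) {
    top <- do.call(cbind, lapply(seq_len(L), function(l) t(cf[, , l])))
    comp <- rbind(top, cbind(diag(p * (L - 1)), matrix(0, p * (L - 1), p)))
    if (L == 1) comp <- top
    max(Mod(eigen(comp, only.values = TRUE)$values))
  }
  for (i in 1:100) {
    r <- radius(coefs)
    if (r <= 0.95) return(coefs)
    coefs <- coefs * (0.95 / r)
  }
  stop_("could not rescale the planted network to a stationary process")
}

# Iterate X_t = sum_l A_l X_{t-l} + eps from a burn-in, recording n_times
# columns.  coefs is cause x effect x lag, so A_l = t(coefs[,,l]).
iterate_var <- function(coefs, n_times, noise_sd, burn_in) {
  p <- dim(coefs)[1]; L <- dim(coefs)[3]
  A <- lapply(seq_len(L), function(l) t(coefs[, , l]))
  hist <- matrix(rnorm(p * L, sd = max(noise_sd, 1e-8)), p, L)
  out <- matrix(0, p, n_times)
  for (step in seq_len(burn_in + n_times)) {
    x <- rnorm(p, sd = noise_sd)
    for (l in seq_len(L)) x <- x + A[[l]] %*% hist[, l]
    hist <- cbind(x, hist[, -L, drop = FALSE])
    if (step > burn_in) out[, step - burn_in] <- x
  }
  out
}

#' Add a square-wave perturbation phase to a simulated series
#'
#' Emulates benchmark data in which an exogenous "drug" shift is applied to
#' a random subset of genes for the first half of the time series and then
#' removed: a constant `magnitude` is added to `round(affected_fraction * p)`
#' genes at all time points in the first half.
#'
#' @param ts an [expression_ts()].
#' @param affected_fraction fraction of genes to shift.
#' @param magnitude size of the constant shift.
#' @param seed integer seed choosing the affected genes.
#' @return The shifted series; affected genes are recorded in
#'   `attr(, "perturbed_genes")`.
#' @export
add_perturbation_phase <- function(ts, affected_fraction = 1/3, magnitude = 1,
                                   seed = 1) {
  check_scalar_prob(affected_fraction, "affected_fraction", open = FALSE)
  d <- dim(ts$values)
  n_aff <- round(affected_fraction * d[1])
  aff <- with_seed(seed, sample.int(d[1], n_aff))
  first_half <- seq_len(floor(d[2] / 2))
  ts$values[aff, first_half, ] <- ts$values[aff, first_half, ] + magnitude
  attr(ts, "perturbed_genes") <- genes.expression_ts(ts)[sort(aff)]
  ts
}
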