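# Core permutation-FDR threshold scan shared by the edge and stability
# rules.  Candidates are the distinct observed magnitudes on either side;
# the returned threshold is the smallest candidate T for which
#
#   #{null > T} / (#{null > T} + #{real > T}) <= target
#
# with strict ">" on both counts and 0/0 defined as 0.  The ratio is always
# 0 at the largest observed value, so the scan terminates.
fdr_scan <- function(real, null, target) {
  cand <- sort(unique(c(real, null)))
  for (T in cand) {
    fp <- sum(null > T)
    tp <- sum(real > T)
    est <- if (fp + tp == 0L) 0 else fp / (fp + tp)
    if (est <= target) {
      return(list(threshold = T, est_fdr = est, survivors = real > T))
    }
  }
  list(threshold = Inf, est_fdr = 0, survivors = rep(FALSE, length(real)))
}

#' Edge-FDR thresholds for one effect gene
#'
#' For each lag, finds the smallest magnitude threshold at which the
#' estimated false discovery proportion — permutation-null coefficients
#' exceeding the threshold over all coefficients exceeding it — is at most
#' `target_fdr`.  An edge into this effect gene survives if its coefficient
#' magnitude clears the threshold at any lag.  Self (autoregressive)
#' coefficients are never edge candidates and must be excluded upstream.
#'
#' @param real_betas numeric matrix of real cross-gene coefficients,
#'   candidate causes in rows and lags in columns (a vector is one lag).
#' @param null_betas matching matrix of permutation-null coefficients.
#' @param target_fdr FDR level in (0, 1); default 0.05.
#' @return A list with `thresholds` and `est_fdr` (per lag), `surviving`
#'   (logical cause x lag matrix), and `edge` (logical vector: survives at
#'   any lag).
#' @export
edge_fdr_threshold <- function(real_betas, null_betas, target_fdr = 0.05) {
  check_scalar_prob(target_fdr, "target_fdr")
  real_betas <- as.matrix(real_betas)
  null_betas <- as.matrix(null_betas)
  if (!identical(dim(real_betas), dim(null_betas)))
    stop_("real and null coefficient sets must have the same shape")
  L <- ncol(real_betas)
  thresholds <- est <- numeric(L)
  surviving <- matrix(FALSE, nrow(real_betas), L,
                      dimnames = dimnames(real_betas))
  for (l in seq_len(L)) {
    s <- fdr_scan(abs(real_betas[, l]), abs(null_betas[, l]), target_fdr)
    thresholds[l] <- s$threshold
    est[l] <- s$est_fdr
    surviving[, l] <- s$survivors
  }
  stopifnot(all(est <= target_fdr))
  list(thresholds = thresholds, est_fdr = est,
       surviving = surviving, edge = rowSums(surviving) > 0)
}

#' Stability-FDR threshold on selection frequencies
#'
#' Pools the per-edge bootstrap selection frequencies from the real data
#' (`pi_real`) and from the permuted stand-in data (`pi_null`) — each at
#' its chosen lag — and finds the smallest frequency cutoff at which the
#' estimated false discovery proportion is at most `target`.  One global
#' cutoff is computed across all edges.
#'
#' @param pi_real,pi_null numeric vectors of selection frequencies in
#'   `[0, 1]`.
#' @param target FDR level in (0, 1); default 0.2.
#' @return A list with `threshold`, `est_fdr`, and `survivors` (logical,
#'   parallel to `pi_real`, strict inequality).
#' @export
stability_fdr_threshold <- function(pi_real, pi_null, target = 0.2) {
  check_scalar_prob(target, "target")
  if (any(pi_real < 0 | pi_real > 1) || any(pi_null < 0 | pi_null > 1))
    stop_("selection frequencies must lie in [0, 1]")
  s <- fdr_scan(pi_real, pi_null, target)
  stopifnot(s$est_fdr <= target)
  s
}
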