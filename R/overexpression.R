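#' Unpenalized pairwise lag-1 autoregression for edge validation
#'
#' Scores a single candidate edge on a held-out (e.g. overexpression)
#' series by ordinary least squares of the effect gene at time `t` on its
#' own value and the cause gene's value at `t - 1`, stacked over
#' replicates, with no intercept and no penalty.  Lag 1 only, regardless
#' of the lag used for network inference: validation series typically have
#' larger time gaps.
#'
#' @param ts a complete [expression_ts()] (centered or raw; typically the
#'   centered validation series).
#' @param cause,effect gene labels, distinct.
#' @return Object of class `pairwise_var_fit`: `c` (self coefficient),
#'   `d` (cross coefficient), `residual_variance`, `n` (rows used).
#' @export
pairwise_var <- function(ts, cause, effect) {
  if (cause == effect) stop_("cause and effect must differ")
  gs <- genes.expression_ts(ts)
  if (!all(c(cause, effect) %in% gs)) stop_("unknown gene label")
  if (!is_complete(ts)) stop_("series has missing entries")
  d <- dim(ts$values)
  rows_t <- rep(2:d[2], each = d[3])
  rows_r <- rep(seq_len(d[3]), times = d[2] - 1)
  y <- ts$values[cbind(match(effect, gs), rows_t, rows_r)]
  X <- cbind(self = ts$values[cbind(match(effect, gs), rows_t - 1L, rows_r)],
             cross = ts$values[cbind(match(cause, gs), rows_t - 1L, rows_r)])
  if (nrow(X) < 3L) stop_("need at least 3 usable rows")
  if (all(X[, "cross"] == 0)) {
    # a silent cause contributes nothing: fit the AR(1) part alone
    c_ <- sum(X[, "self"] * y) / sum(X[, "self"]^2)
    b <- c(c_, 0)
  } else {
    qx <- qr(X)
    if (qx$rank < 2L)
      stop_("degenerate fit: cause and effect lagged profiles are collinear")
    b <- qr.coef(qx, y)
  }
  res <- y - X %*% b
  structure(list(c = unname(b[1]), d = unname(b[2]),
                 residual_variance = sum(res^2) / (nrow(X) - 2L),
                 n = nrow(X), cause = cause, effect = effect),
            class = "pairwise_var_fit")
}

#' @export
print.pairwise_var_fit <- function(x, ...) {
  cat(sprintf("pairwise VAR %s -> %s: c = %.4g, d = %.4g (n = %d)\n",
              x$cause, x$effect, x$c, x$d, x$n))
  invisible(x)
}

#' Concordance between inferred edge signs and validation coefficients
#'
#' For each overexpressed cause gene, regresses the pairwise validation
#' coefficients `d` on encodings of the inferred network's edge signs:
#' a one-hot indicator of positive edges, a one-hot indicator of negative
#' edges, and a signed encoding (+1 positive, 0 no edge, -1 negative).
#' A positive slope in the positive-indicator (or signed) regression means
#' edges the network calls activating have systematically larger
#' validation coefficients.  Slopes get ordinary two-sided t-test
#' p-values, Benjamini-Hochberg adjusted across cause genes within each
#' encoding; causes with fewer than 3 scored pairs (or a constant
#' predictor) are flagged underpowered and carry no p-value.
#'
#' @param network network data frame (`cause`, `effect`, `sign`) or a
#'   [stabvar()] fit.
#' @param coefs data frame with columns `cause`, `effect`, `d`: one
#'   pairwise validation coefficient per scored pair (pairs absent from
#'   the network count as sign 0).
#' @return Data frame with one row per (cause, encoding): `slope`, `p`,
#'   `p_adj`, `n`, `underpowered`.
#' @export
sign_concordance <- function(network, coefs) {
  if (inherits(network, "stabvar")) network <- as.data.frame(network)
  coefs <- as.data.frame(coefs, stringsAsFactors = FALSE)
  if (!all(c("cause", "effect", "d") %in% names(coefs)))
    stop_("coefs needs columns cause, effect, d")
  nk <- paste(network$cause, network$effect, sep = "\r")
  sgn <- setNames(network$sign, nk)
  coefs$sign <- unname(sgn[paste(coefs$cause, coefs$effect, sep = "\r")])
  coefs$sign[is.na(coefs$sign)] <- 0
  encodings <- list(positive = function(s) as.numeric(s > 0),
                    negative = function(s) as.numeric(s < 0),
                    signed = function(s) s)
  out <- NULL
  for (cg in unique(coefs$cause)) {
    sub <- coefs[coefs$cause == cg, ]
    for (enc in names(encodings)) {
      xv <- encodings[[enc]](sub$sign)
      under <- nrow(sub) < 3L || var(xv) == 0
      slope <- p <- NA_real_
      if (!under) {
        fit <- lm(sub$d ~ xv)
        sm <- summary(fit)$coefficients
        slope <- sm["xv", "Estimate"]
        p <- sm["xv", "Pr(>|t|)"]
      }
      out <- rbind(out, data.frame(cause = cg, encoding = enc, slope = slope,
                                   p = p, n = nrow(sub), underpowered = under,
                                   stringsAsFactors = FALSE))
    }
  }
  for (enc in unique(out$encoding)) {
    i <- out$encoding == enc
    out$p_adj[i] <- p.adjust(out$p[i], method = "BH")
  }
  out
}
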