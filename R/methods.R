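#' @export
print.stabvar <- function(x, ...) {
  d <- x$dims
  cat("Stability-selected elastic-net VAR network\n")
  cat(sprintf("  data: %d genes, %d time points, %d replicate%s (%d rows, lag %d)\n",
              d$p, d$T, d$R, if (d$R == 1) "" else "s", d$N, d$L))
  cat(sprintf("  penalty: lambda = %g, a = %g (%s%s)\n", x$lambda, x$a,
              x$penalty, if (is.null(x$loocv)) ", fixed" else ", LOOCV"))
  cat(sprintf("  bootstrap: B = %d, edge FDR <= %g\n", x$B, x$edge_fdr))
  if (!is.null(x$network)) {
    cat(sprintf("  stability threshold: pi > %g (stability FDR <= %g)\n",
                x$stability_threshold, x$stability_fdr))
    cat(sprintf("  network: %d directed edge%s\n", nrow(x$network),
                if (nrow(x$network) == 1) "" else "s"))
  } else {
    cat("  network: not thresholded (stability_null = FALSE)\n")
  }
  invisible(x)
}

#' Summarize a fitted network
#'
#' @param object a [stabvar()] fit.
#' @param ... unused.
#' @return A `summary.stabvar` object: edge, sign and degree summaries plus
#'   the strongest edges.
#' @export
summary.stabvar <- function(object, ...) {
  net <- object$network
  s <- list(fit = object)
  if (!is.null(net) && nrow(net)) {
    s$n_edges <- nrow(net)
    s$n_causes <- length(unique(net$cause))
    s$n_effects <- length(unique(net$effect))
    s$sign_table <- table(factor(net$sign, levels = c(-1, 1),
                                 labels = c("inhibitory", "activating")))
    s$lag_table <- table(net$lag)
    s$top <- head(net, 10)
    s$density <- nrow(net) / (object$dims$p * (object$dims$p - 1))
  }
  class(s) <- "summary.stabvar"
  s
}

#' @export
print.summary.stabvar <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$n_edges)) {
    cat(sprintf("  %d causes -> %d effects; density %.3g\n",
                x$n_causes, x$n_effects, x$density))
    cat("  signs: ", paste(names(x$sign_table), x$sign_table,
                           sep = " = ", collapse = ", "), "\n")
    cat("  lags:  ", paste(names(x$lag_table), x$lag_table,
                           sep = " = ", collapse = ", "), "\n")
    cat("  strongest edges:\n")
    print(x$top, row.names = FALSE)
  }
  invisible(x)
}

#' Extract fitted VAR coefficients
#'
#' @param object a [stabvar()] fit.
#' @param type `"original"` for the single full-data elastic-net fit,
#'   `"mean"` for the mean across bootstrap fits (zeros included).
#' @param ... unused.
#' @return A `p x p x L` array indexed (cause, effect, lag); diagonal
#'   entries are the self (autoregressive) coefficients for `"original"`
#'   and `NA` for `"mean"` (self lags are never bootstrapped edges).
#' @export
coef.stabvar <- function(object, type = c("original", "mean"), ...) {
  type <- match.arg(type)
  if (type == "original") object$coefficients else object$mean_coefficients
}

#' One-step-ahead predictions from the fitted VAR
#'
#' Applies the full-data coefficient tensor to the lagged values of a
#' (complete, centered) series, producing the model's prediction of every
#' gene at every time point with a full lag history.
#'
#' @param object a [stabvar()] fit.
#' @param newdata optional [expression_ts()] over the same genes; defaults
#'   to the training series.
#' @param ... unused.
#' @return A list with `predicted` (`N x p` matrix), `observed`, and
#'   `row_index`.
#' @export
predict.stabvar <- function(object, newdata = NULL, ...) {
  ts <- newdata %||% object$ts
  if (!identical(genes.expression_ts(ts), object$genes))
    stop_("newdata genes differ from the fitted genes")
  gs <- object$genes
  pred <- obs <- NULL
  for (g in gs) {
    d <- build_design(ts, g, object$dims$L)
    b <- flatten_coef(object$coefficients, g, gs)
    pred <- cbind(pred, drop(d$predictors %*% b))
    obs <- cbind(obs, d$response)
  }
  colnames(pred) <- colnames(obs) <- gs
  list(predicted = pred, observed = obs,
       row_index = build_design(ts, gs[1], object$dims$L)$row_index)
}

#' @export
fitted.stabvar <- function(object, ...) predict(object)$predicted

#' Residuals of the fitted VAR on the training series
#'
#' @param object a [stabvar()] fit.
#' @param ... unused.
#' @return `N x p` matrix of one-step-ahead residuals.
#' @export
residuals.stabvar <- function(object, ...) {
  pr <- predict(object)
  pr$observed - pr$predicted
}

#' Plot real against null selection-frequency distributions
#'
#' Overlaid histograms of the bootstrap selection frequencies (at each
#' edge's chosen lag) from the real data and from the permuted stand-in
#' data, with the stability threshold marked.
#'
#' @param x a [stabvar()] fit with a null stability run.
#' @param breaks histogram breaks.
#' @param ... passed to [graphics::hist()].
#' @export
plot.stabvar <- function(x, breaks = 20, ...) {
  pi_real <- at_chosen_lag(x$frequencies, x$lag_choice)
  pi_real <- pi_real[!is.na(pi_real)]
  if (is.null(x$null_frequencies)) {
    hist(pi_real, breaks = breaks, col = "grey40", border = NA,
         main = "Bootstrap selection frequencies",
         xlab = "selection frequency", ...)
    return(invisible(x))
  }
  pi_null <- at_chosen_lag(x$null_frequencies, x$null_lag_choice)
  pi_null <- pi_null[!is.na(pi_null)]
  br <- seq(0, 1, length.out = breaks + 1)
  hr <- hist(pi_real, breaks = br, plot = FALSE)
  hn <- hist(pi_null, breaks = br, plot = FALSE)
  plot(hr, col = grDevices::adjustcolor("steelblue", 0.6), border = NA,
       ylim = c(0, max(hr$counts, hn$counts)),
       main = "Selection frequencies: real vs permuted",
       xlab = "selection frequency", ...)
  plot(hn, col = grDevices::adjustcolor("firebrick", 0.5), border = NA, add = TRUE)
  abline(v = x$stability_threshold, lty = 2)
  legend("topright", fill = c("steelblue", "firebrick"), bty = "n",
         legend = c("real", "permuted null"))
  invisible(x)
}

#' Simulate new series from the fitted VAR
#'
#' Iterates the full-data coefficient tensor with Gaussian innovations
#' whose per-gene standard deviations match the training residuals,
#' after a burn-in from a random start.
#'
#' @param object a [stabvar()] fit.
#' @param nsim number of series to generate.
#' @param seed integer seed.
#' @param n_times,n_reps dimensions of each simulated series; default the
#'   training dimensions.
#' @param ... unused.
#' @return A list of `nsim` [expression_ts()] objects.
#' @export
simulate.stabvar <- function(object, nsim = 1, seed = 1,
                             n_times = NULL, n_reps = NULL, ...) {
  n_times <- n_times %||% object$dims$T
  n_reps <- n_reps %||% object$dims$R
  sds <- apply(residuals(object), 2, sd)
  coefs <- object$coefficients
  p <- length(object$genes)
  with_seed(seed, {
    lapply(seq_len(nsim), function(k) {
      vals <- array(0, c(p, n_times, n_reps))
      for (r in seq_len(n_reps))
        vals[, , r] <- iterate_var_sd(coefs, n_times, sds, 200)
      expression_ts(vals, genes = object$genes)
    })
  })
}

# iterate_var with per-gene innovation scales
iterate_var_sd <- function(coefs, n_times, sds, burn_in) {
  p <- dim(coefs)[1]; L <- dim(coefs)[3]
  A <- lapply(seq_len(L), function(l) t(coefs[, , l]))
  sds <- pmax(sds, 1e-8)
  hist <- matrix(rnorm(p * L, sd = sds), p, L)
  out <- matrix(0, p, n_times)
  for (step in seq_len(burn_in + n_times)) {
    x <- rnorm(p, sd = sds)
    for (l in seq_len(L)) x <- x + A[[l]] %*% hist[, l]
    hist <- cbind(x, hist[, -L, drop = FALSE])
    if (step > burn_in) out[, step - burn_in] <- x
  }
  out
}

#' @export
as.data.frame.stabvar <- function(x, ...) {
  x$network %||% stop_("fit has no thresholded network (stability_null = FALSE)")
}

#' Write / read a network edge table
#'
#' Tab-separated with header `cause effect lag sign effect_size
#' selection_frequency`, one edge per line, sorted by descending selection
#' frequency then lexicographically.
#'
#' @param network a network data frame (or a [stabvar()] fit).
#' @param path file path.
#' @export
write_network <- function(network, path) {
  if (inherits(network, "stabvar")) network <- as.data.frame(network)
  write.table(format(network, digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export full-data coefficients with their null thresholds
#'
#' Writes one row per (cause, effect, lag) from the single full-data
#' elastic-net fit: the coefficient, the permutation-null magnitude
#' threshold for that (effect, lag), and whether the coefficient survives
#' it.  Self (autoregressive) terms are excluded — they are never edge
#' candidates.
#'
#' @param object a [stabvar()] fit.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_coefficients <- function(object, path) {
  gs <- object$genes
  p <- length(gs); L <- object$dims$L
  rows <- expand.grid(cause = seq_len(p), effect = seq_len(p),
                      lag = seq_len(L), KEEP.OUT.ATTRS = FALSE)
  rows <- rows[rows$cause != rows$effect, ]
  co <- object$coefficients[cbind(rows$cause, rows$effect, rows$lag)]
  thr <- object$enet$thresholds[cbind(rows$effect, rows$lag)]
  out <- data.frame(cause = gs[rows$cause], effect = gs[rows$effect],
                    lag = rows$lag, coefficient = co, null_threshold = thr,
                    survives = abs(co) > thr)
  out <- out[order(out$effect, out$lag, out$cause), ]
  write.table(format(out, digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  num <- intersect(c("lag", "sign", "effect_size", "selection_frequency",
                     "coefficient_magnitude", "score"), names(df))
  df[num] <- lapply(df[num], as.numeric)
  df
}
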