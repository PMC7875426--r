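#' Build the lagged regression problem for one effect gene
#'
#' Converts a complete, centered time series into the regression used for
#' Granger-causal fitting of a single effect gene: the response stacks the
#' gene's expression at times `t = L+1, ..., T` over replicates (time-major,
#' replicates in declared order), and the predictor matrix holds the lagged
#' expression of every gene, lag-major (all genes at lag 1, then all genes
#' at lag 2, ...).  With `T` time points and `R` replicates the design has
#' `N = R * (T - L)` rows and `L * p` columns; the effect gene's own lagged
#' columns are included and carry the autoregressive coefficients.
#'
#' @param ts a complete [expression_ts()].
#' @param effect_gene gene label.
#' @param lag maximum lag `L` (must satisfy `T >= L + 1`).
#' @return An object of class `lagged_design`: a list with `effect_gene`,
#'   `response` (length `N`), `predictors` (`N x L*p` matrix),
#'   `column_index` (data frame mapping columns to (gene, lag)),
#'   `row_index` (data frame mapping rows to (time, replicate)),
#'   `N`, `L`, and `genes`.
#' @export
#' @examples
#' x <- array(c(1, 4, 2, 5, 3, 6), c(2, 3, 1),
#'            dimnames = list(c("g1", "g2"), NULL, NULL))
#' d <- build_design(expression_ts(x), "g1", lag = 2)
#' d$response      # 3
#' d$predictors    # lag-1 (g1, g2) then lag-2 (g1, g2): 2 5 1 4
build_design <- function(ts, effect_gene, lag) {
  if (!is_complete(ts)) stop_("design requires a complete series")
  d <- dim(ts$values)
  gs <- genes.expression_ts(ts)
  if (!effect_gene %in% gs) stop_("unknown effect gene: ", effect_gene)
  lag <- as.integer(lag)
  if (lag < 1L) stop_("lag must be >= 1")
  if (d[2] < lag + 1L)
    stop_(sprintf("need T >= L + 1 time points (T = %d, L = %d)", d[2], lag))
  p <- d[1]; Tn <- d[2]; R <- d[3]
  tt <- seq.int(lag + 1L, Tn)
  N <- R * length(tt)
  # rows: time-major, replicates in declared order within each time
  row_time <- rep(tt, each = R)
  row_rep <- rep(seq_len(R), times = length(tt))
  y <- ts$values[cbind(match(effect_gene, gs), row_time, row_rep)]
  X <- matrix(0, N, lag * p)
  col_gene <- rep(seq_len(p), times = lag)
  col_lag <- rep(seq_len(lag), each = p)
  for (j in seq_len(lag * p)) {
    X[, j] <- ts$values[cbind(col_gene[j], row_time - col_lag[j], row_rep)]
  }
  colnames(X) <- paste0(gs[col_gene], "_lag", col_lag)
  structure(list(
    effect_gene = effect_gene,
    response = y,
    predictors = X,
    column_index = data.frame(gene = gs[col_gene], lag = col_lag,
                              stringsAsFactors = FALSE),
    row_index = data.frame(time = ts$times[row_time],
                           replicate = reps.expression_ts(ts)[row_rep],
                           stringsAsFactors = FALSE),
    N = N, L = lag, genes = gs
  ), class = "lagged_design")
}

#' @export
print.lagged_design <- function(x, ...) {
  cat(sprintf("lagged_design for effect gene '%s': N = %d rows, %d columns (L = %d, p = %d)\n",
              x$effect_gene, x$N, ncol(x$predictors), x$L, length(x$genes)))
  invisible(x)
}

# Flatten a (cause x effect x lag) coefficient array into the lag-major
# column order of build_design() for one effect gene.  The diagonal entries
# of each lag slice hold the self (autoregressive) coefficients.
flatten_coef <- function(coefs, effect_gene, genes) {
  L <- dim(coefs)[3]
  g <- match(effect_gene, genes)
  as.vector(vapply(seq_len(L), function(l) coefs[, g, l], numeric(length(genes))))
}

# Inverse of flatten_coef: shape a design-ordered coefficient vector into a
# (cause x lag) matrix for one effect gene.
unflatten_coef <- function(b, design) {
  matrix(b, ncol = design$L,
         dimnames = list(design$genes, paste0("lag", seq_len(design$L))))
}
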