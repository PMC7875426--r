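#' Draw bootstrap row-index sets
#'
#' Draws `B` multisets of `N` row indices, each sampled uniformly with
#' replacement.  Index sets are drawn sequentially, so the first `B0 < B`
#' sets for a given seed are a prefix of the sets drawn for `B`; this is
#' what makes checkpoint resumption exact.
#'
#' @param N number of design rows.
#' @param B number of bootstrap samples.
#' @param seed integer seed.
#' @return Integer `B x N` matrix; row `j` is the multiset `I_j`.
#' @export
draw_bootstrap_indices <- function(N, B, seed) {
  if (N < 1 || B < 1) stop_("N and B must be positive")
  with_seed(seed, {
    m <- matrix(0L, B, N)
    for (j in seq_len(B)) m[j, ] <- sample.int(N, N, replace = TRUE)
    m
  })
}

# Per-gene fixed quantities reused across bootstraps.
prepare_gene_matrices <- function(data_ts, null_ts, gene, lag) {
  dr <- build_design(data_ts, gene, lag)
  dn <- build_design(null_hybrid_ts(data_ts, null_ts, gene), gene, lag)
  list(gene = gene, Xr = dr$predictors, Xn = dn$predictors, y = dr$response,
       column_index = dr$column_index, N = dr$N, L = dr$L, genes = dr$genes,
       self = which(dr$column_index$gene == gene))
}

# Bootstrap selection frequencies and mean coefficients for one effect
# gene.  A bootstrap fit is the weighted fit with integer resampling
# weights (identical to fitting on the duplicated rows).  Each bootstrap's
# edge-FDR threshold compares that bootstrap's real and null coefficient
# magnitudes, using the same row multiset on both sides.
gene_bootstrap_counts <- function(pm, index_sets, lambda, a, edge_fdr) {
  B <- nrow(index_sets)
  p <- length(pm$genes); L <- pm$L
  cross <- setdiff(seq_len(ncol(pm$Xr)), pm$self)
  counts <- matrix(0, p, L) # cause x lag (self row stays zero)
  sums <- matrix(0, p, L)
  for (j in seq_len(B)) {
    w <- tabulate(index_sets[j, ], pm$N)
    sw <- sqrt(w)
    wy <- w * pm$y
    br <- .cd_enet_gram(crossprod(pm$Xr * sw), crossprod(pm$Xr, wy)[, 1],
                        lambda, a, numeric(ncol(pm$Xr)), 1e-12, 100000L)
    bn <- .cd_enet_gram(crossprod(pm$Xn * sw), crossprod(pm$Xn, wy)[, 1],
                        lambda, a, numeric(ncol(pm$Xn)), 1e-12, 100000L)
    rb <- matrix(br[cross], ncol = L)
    nb <- matrix(bn[cross], ncol = L)
    surv <- edge_fdr_threshold(rb, nb, edge_fdr)$surviving
    cause <- matrix(pm$column_index$gene[cross], ncol = L)[, 1]
    ci <- match(cause, pm$genes)
    counts[ci, ] <- counts[ci, ] + surv
    sums[ci, ] <- sums[ci, ] + rb
  }
  list(gene = pm$gene, counts = counts, sums = sums, B = B)
}

#' Bootstrap selection frequencies for every candidate edge
#'
#' Runs the elastic-net fit plus per-bootstrap edge-FDR thresholding over
#' all bootstrap row multisets and all effect genes, and returns each
#' candidate edge's selection frequency (fraction of bootstrap networks in
#' which it survives, per lag) together with its mean coefficient across
#' all bootstrap fits (zeros included).  The same row multisets are applied
#' to the real design and to its permutation-null counterpart.
#'
#' To compute the null frequency distribution for the stability FDR, call
#' this with the second permuted series in the `data_ts` role and the first
#' permuted series as `null_ts`.
#'
#' @param data_ts complete centered series playing the data role.
#' @param null_ts independently permuted series providing the null lagged
#'   profiles (see [permute_profiles()]).
#' @param index_sets output of [draw_bootstrap_indices()].
#' @param lambda,a penalty tuned on the original data.
#' @param lag maximum lag.
#' @param edge_fdr per-bootstrap edge-FDR level.
#' @param cores genes are fit independently and may be spread over this
#'   many forked workers; results are identical for any worker count.
#' @param checkpoint optional path: per-gene accumulators are saved there
#'   as genes complete, and a matching file is loaded to skip finished
#'   genes on restart.
#' @return A list with `frequencies` and `mean_coefficients`, both
#'   `p x p x L` arrays indexed cause, effect, lag (self entries `NA`).
#' @export
selection_frequencies <- function(data_ts, null_ts, index_sets, lambda, a,
                                  lag = 2, edge_fdr = 0.05, cores = 1L,
                                  checkpoint = NULL) {
  gs <- genes.expression_ts(data_ts)
  p <- length(gs)
  key <- c(dim(data_ts$values), lag, lambda, a, dim(index_sets),
           sum(as.double(index_sets)), sum(data_ts$values^2), sum(null_ts$values^2))
  state <- NULL
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    st <- tryCatch(readRDS(checkpoint), error = function(e) NULL)
    if (!is.null(st) && isTRUE(all.equal(st$key, key))) state <- st
  }
  freq <- state$freq %||% array(NA_real_, c(p, p, lag), dimnames = list(gs, gs, NULL))
  sums <- state$sums %||% array(NA_real_, c(p, p, lag), dimnames = list(gs, gs, NULL))
  done <- state$done %||% character(0)
  todo <- setdiff(gs, done)
  run_gene <- function(g) {
    pm <- prepare_gene_matrices(data_ts, null_ts, g, lag)
    gene_bootstrap_counts(pm, index_sets, lambda, a, edge_fdr)
  }
  for (chunk in split(todo, ceiling(seq_along(todo) / max(1L, cores)))) {
    res <- if (cores > 1L) parallel::mclapply(chunk, run_gene, mc.cores = cores)
           else lapply(chunk, run_gene)
    for (r in res) {
      gi <- match(r$gene, gs)
      f <- r$counts / r$B; f[gi, ] <- NA_real_
      s <- r$sums / r$B; s[gi, ] <- NA_real_
      freq[, gi, ] <- f
      sums[, gi, ] <- s
      done <- c(done, r$gene)
    }
    if (!is.null(checkpoint))
      saveRDS(list(key = key, freq = freq, sums = sums, done = done), checkpoint)
  }
  list(frequencies = freq, mean_coefficients = sums, B = nrow(index_sets))
}

#' Null selection frequencies from a second, independent permutation
#'
#' Convenience wrapper: reruns the full stability-selection machinery with
#' the second permuted series standing in for the data and the first
#' permuted series providing the permutation null, using the same bootstrap
#' row multisets as the real run.
#'
#' @param second_permuted,first_permuted two series obtained from the
#'   original data by [permute_profiles()] with different seeds.
#' @inheritParams selection_frequencies
#' @export
null_selection_frequencies <- function(second_permuted, first_permuted,
                                       index_sets, lambda, a, lag = 2,
                                       edge_fdr = 0.05, cores = 1L,
                                       checkpoint = NULL) {
  if (identical(second_permuted$values, first_permuted$values))
    stop_("the two permuted series are identical; use independent seeds")
  selection_frequencies(second_permuted, first_permuted, index_sets, lambda,
                        a, lag, edge_fdr, cores, checkpoint)
}

#' Choose each edge's lag by largest mean bootstrap coefficient
#'
#' For every ordered gene pair the forwarded selection frequency is the one
#' at the lag whose mean bootstrap coefficient has the largest magnitude;
#' exact ties go to the smaller lag.  The same rule is applied separately
#' to the null side with the null mean coefficients.
#'
#' @param mean_coefficients `p x p x L` array (cause, effect, lag).
#' @return Integer `p x p` matrix of chosen lags (`NA` on the diagonal).
#' @export
choose_lag <- function(mean_coefficients) {
  p <- dim(mean_coefficients)[1]
  out <- matrix(NA_integer_, p, p, dimnames = dimnames(mean_coefficients)[1:2])
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    v <- abs(mean_coefficients[i, j, ])
    if (all(is.na(v))) next
    out[i, j] <- which.max(v) # first max: ties go to the smaller lag
  }
  out
}

at_chosen_lag <- function(arr, lag_choice) {
  p <- dim(arr)[1]
  idx <- which(!is.na(lag_choice))
  out <- matrix(NA_real_, p, p, dimnames = dimnames(arr)[1:2])
  out[idx] <- arr[cbind(((idx - 1) %% p) + 1, ((idx - 1) %/% p) + 1,
                        lag_choice[idx])]
  out
}

#' Assemble the final directed network at a stability threshold
#'
#' Keeps every ordered gene pair whose selection frequency at its chosen
#' lag strictly exceeds `threshold`; sign and effect size come from the
#' mean bootstrap coefficient at that lag.  Self edges are excluded by
#' construction.
#'
#' @param frequencies,mean_coefficients `p x p x L` arrays from
#'   [selection_frequencies()].
#' @param lag_choice matrix from [choose_lag()].
#' @param threshold stability (selection-frequency) cutoff.
#' @return Data frame `cause, effect, lag, sign, effect_size,
#'   selection_frequency`, sorted by descending frequency then
#'   lexicographically.
#' @export
assemble_network <- function(frequencies, mean_coefficients, lag_choice,
                             threshold) {
  pi_star <- at_chosen_lag(frequencies, lag_choice)
  mc_star <- at_chosen_lag(mean_coefficients, lag_choice)
  keep <- which(!is.na(pi_star) & pi_star > threshold, arr.ind = TRUE)
  gs <- rownames(pi_star)
  net <- data.frame(
    cause = gs[keep[, 1]], effect = gs[keep[, 2]],
    lag = lag_choice[keep], sign = sign(mc_star[keep]),
    effect_size = mc_star[keep], selection_frequency = pi_star[keep],
    stringsAsFactors = FALSE
  )
  net[order(-net$selection_frequency, net$cause, net$effect), , drop = FALSE]
}

#' Infer a directed gene network by stability-selected elastic-net VAR
#'
#' Fits, for every effect gene, an elastic-net vector autoregression of its
#' expression on the lagged expression of all genes; calibrates a per-gene,
#' per-lag coefficient threshold against a permutation null (edge FDR);
#' repeats the thresholded inference over `boots` bootstrap resamples to
#' obtain each candidate edge's selection frequency; and finally calibrates
#' a network-wide frequency cutoff against the selection frequencies
#' obtained from a second, independent permutation of the data (stability
#' FDR).  Edges above the cutoff form the reported signed, lagged network.
#'
#' The penalty pair `(lambda, a)` is tuned once on the original data by
#' leave-one-out cross-validation and reused for every permutation and
#' bootstrap fit.
#'
#' @param x an [expression_ts()]; it is completed ([interpolate_missing()]
#'   must have been run if entries are missing) and centered internally.
#' @param lag maximum lag `L` (default 2).
#' @param boots number of bootstrap samples `B` (default 1000; 100 is a
#'   documented fast mode with nearly equivalent networks).
#' @param edge_fdr per-bootstrap coefficient FDR level (default 0.05).
#' @param stability_fdr selection-frequency FDR level (default 0.2).
#' @param lambda_grid,a_grid LOOCV grids; defaults
#'   `10^(-4:0)` and `seq(0.1, 0.9, 0.2)`.
#' @param lambda,a optional fixed penalty, skipping LOOCV.
#' @param penalty `"elastic_net"` (default), `"lasso"` (forces `a = 1`) or
#'   `"ridge"` (forces `a = 0`).
#' @param stability_null set `FALSE` to skip the null (second-permutation)
#'   stability run; the object then carries selection frequencies and
#'   rankings but no stability threshold or final network.
#' @param seed integer seed; permutation and bootstrap streams are derived
#'   from it.  Defaults to 42 with a message.
#' @param seeds optional list overriding the derived streams, with elements
#'   `permutation1`, `permutation2`, `bootstrap`.
#' @param cores forked workers for the bootstrap loops (results are
#'   independent of the worker count).
#' @param checkpoint_dir optional directory for resumable bootstrap
#'   checkpoints.
#' @param verbose print per-stage progress.
#' @return An object of class `stabvar`; see [print.stabvar()],
#'   [summary.stabvar()], [coef.stabvar()], [predict.stabvar()],
#'   [plot.stabvar()], [simulate.stabvar()], [edge_ranking()],
#'   [write_network()].
#' @export
#' @examples
#' sim <- simulate_var(p = 6, density = 0.15, n_times = 12, n_reps = 3, seed = 7)
#' fit <- stabvar(sim$ts, boots = 25, seed = 11, lambda = 0.01, a = 0.5)
#' fit
#' head(as.data.frame(fit))
stabvar <- function(x, lag = 2, boots = 1000,
                    edge_fdr = 0.05, stability_fdr = 0.2,
                    lambda_grid = default_lambda_grid(),
                    a_grid = default_a_grid(),
                    lambda = NULL, a = NULL,
                    penalty = c("elastic_net", "lasso", "ridge"),
                    stability_null = TRUE,
                    seed = NULL, seeds = NULL, cores = 1L,
                    checkpoint_dir = NULL, verbose = FALSE) {
  cl <- match.call()
  penalty <- match.arg(penalty)
  if (!inherits(x, "expression_ts")) stop_("x must be an expression_ts")
  if (is.null(seed) && is.null(seeds)) {
    seed <- 42L
    message("no seed supplied; using the default seed 42")
  }
  if (is.null(seeds)) {
    sub <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 3L))
    seeds <- list(permutation1 = sub[1], permutation2 = sub[2], bootstrap = sub[3])
  }
  if (identical(seeds$permutation1, seeds$permutation2))
    stop_("the two permutation seeds must differ")
  say <- function(...) if (verbose) message(sprintf(...))

  if (!is_complete(x))
    stop_("series has missing entries; run interpolate_missing() first")
  x <- drop_constant_genes(x)
  gaps <- diff(x$times)
  if (max(gaps) / min(gaps) > 4)
    warning("time points are very unevenly spaced (max/min gap ratio > 4); ",
            "the lagged model assumes similar causal effects across gaps",
            call. = FALSE)
  x <- center_profiles(x)
  gs <- genes.expression_ts(x)
  p <- length(gs)
  if (p < 2L) stop_("need at least two genes")

  if (penalty == "lasso") a_grid <- 1
  if (penalty == "ridge") a_grid <- 0
  designs <- lapply(gs, function(g) build_design(x, g, lag))
  names(designs) <- gs
  N <- designs[[1]]$N

  loocv <- NULL
  if (is.null(lambda) || is.null(a)) {
    say("LOOCV over %d x %d penalty grid ...", length(lambda_grid), length(a_grid))
    loocv <- loocv_select(designs, lambda_grid, a_grid)
    lambda <- loocv$lambda
    a <- loocv$a
  }
  if (penalty == "lasso" && a != 1) stop_("lasso penalty requires a = 1")
  if (penalty == "ridge" && a != 0) stop_("ridge penalty requires a = 0")
  say("penalty: lambda = %g, a = %g", lambda, a)

  perm1 <- permute_profiles(x, seeds$permutation1)
  # full-data fits: coefficient tensor and the unbootstrapped (baseline) network
  coefs <- array(0, c(p, p, lag), dimnames = list(gs, gs, NULL))
  null_coefs <- array(0, c(p, p, lag), dimnames = list(gs, gs, NULL))
  for (g in gs) {
    b <- enet_fit(designs[[g]], lambda, a)
    bn <- fit_null_coefficients(x, perm1, g, lambda, a, lag)
    coefs[, g, ] <- matrix(b, ncol = lag)
    null_coefs[, g, ] <- matrix(bn, ncol = lag)
  }
  enet <- enet_baseline(coefs, null_coefs, gs, edge_fdr)

  say("bootstrap stability selection (B = %d) ...", boots)
  idx <- draw_bootstrap_indices(N, boots, seeds$bootstrap)
  ckpt <- function(tag) if (is.null(checkpoint_dir)) NULL else {
    dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
    file.path(checkpoint_dir, paste0(tag, ".rds"))
  }
  real <- selection_frequencies(x, perm1, idx, lambda, a, lag, edge_fdr,
                                cores, ckpt("bootstrap-real"))
  lag_choice <- choose_lag(real$mean_coefficients)

  null <- NULL; null_lag_choice <- NULL; thr <- NULL
  network <- NULL
  if (stability_null) {
    say("null stability run (second permutation) ...")
    perm2 <- permute_profiles(x, seeds$permutation2)
    null <- null_selection_frequencies(perm2, perm1, idx, lambda, a, lag,
                                       edge_fdr, cores, ckpt("bootstrap-null"))
    null_lag_choice <- choose_lag(null$mean_coefficients)
    pi_real <- at_chosen_lag(real$frequencies, lag_choice)
    pi_null <- at_chosen_lag(null$frequencies, null_lag_choice)
    thr <- stability_fdr_threshold(pi_real[!is.na(pi_real)],
                                   pi_null[!is.na(pi_null)], stability_fdr)
    network <- assemble_network(real$frequencies, real$mean_coefficients,
                                lag_choice, thr$threshold)
    say("stability threshold %g -> %d edges", thr$threshold, nrow(network))
  }

  structure(list(
    network = network,
    stability_threshold = thr$threshold,
    est_stability_fdr = thr$est_fdr,
    frequencies = real$frequencies,
    null_frequencies = null$frequencies,
    mean_coefficients = real$mean_coefficients,
    null_mean_coefficients = null$mean_coefficients,
    lag_choice = lag_choice,
    null_lag_choice = null_lag_choice,
    coefficients = coefs,
    null_coefficients = null_coefs,
    enet = enet,
    lambda = lambda, a = a, penalty = penalty, loocv = loocv,
    edge_fdr = edge_fdr, stability_fdr = stability_fdr,
    B = boots, seeds = seeds, genes = gs,
    dims = list(p = p, T = dim(x)[2], R = dim(x)[3], N = N, L = lag),
    ts = x, call = cl
  ), class = "stabvar")
}

# Baseline single-fit network: per effect gene and lag, threshold the
# full-data coefficients against the full-data permutation-null fit.
enet_baseline <- function(coefs, null_coefs, gs, edge_fdr) {
  p <- length(gs); L <- dim(coefs)[3]
  thresholds <- matrix(NA_real_, p, L, dimnames = list(gs, NULL))
  est <- matrix(NA_real_, p, L, dimnames = list(gs, NULL))
  edges <- NULL
  for (g in seq_len(p)) {
    rb <- matrix(coefs[-g, g, ], ncol = L)
    nb <- matrix(null_coefs[-g, g, ], ncol = L)
    ef <- edge_fdr_threshold(rb, nb, edge_fdr)
    thresholds[g, ] <- ef$thresholds
    est[g, ] <- ef$est_fdr
    if (any(ef$edge)) {
      causes <- gs[-g][ef$edge]
      cc <- matrix(rb[ef$edge, , drop = FALSE], ncol = L)
      lstar <- apply(abs(cc), 1, which.max)
      cstar <- cc[cbind(seq_along(lstar), lstar)]
      edges <- rbind(edges, data.frame(
        cause = causes, effect = gs[g], lag = lstar, sign = sign(cstar),
        effect_size = cstar, coefficient_magnitude = abs(cstar),
        stringsAsFactors = FALSE))
    }
  }
  if (!is.null(edges))
    edges <- edges[order(-edges$coefficient_magnitude, edges$cause, edges$effect), ]
  list(network = edges, thresholds = thresholds, est_fdr = est)
}

#' Rank all candidate edges of a fitted model
#'
#' `"frequency"` ranks ordered gene pairs by bootstrap selection frequency
#' at each pair's chosen lag (the stability-selected ranking);
#' `"coefficient"` ranks them by the magnitude of the single full-data
#' elastic-net coefficient, maximized over lags (the unbootstrapped
#' baseline).  Ties are ordered lexicographically.
#'
#' @param object a [stabvar()] fit.
#' @param method `"frequency"` or `"coefficient"`.
#' @return Data frame `cause, effect, score` in rank order.
#' @export
edge_ranking <- function(object, method = c("frequency", "coefficient")) {
  method <- match.arg(method)
  gs <- object$genes
  score <- if (method == "frequency") {
    at_chosen_lag(object$frequencies, object$lag_choice)
  } else {
    apply(abs(object$coefficients), c(1, 2), max)
  }
  idx <- which(!diag(TRUE, length(gs)), arr.ind = TRUE)
  out <- data.frame(cause = gs[idx[, 1]], effect = gs[idx[, 2]],
                    score = score[idx], stringsAsFactors = FALSE)
  out[order(-out$score, out$cause, out$effect), , drop = FALSE]
}
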