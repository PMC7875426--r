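test_that("bootstrap index sets behave like sampling with replacement", {
  expect_equal(draw_bootstrap_indices(1, 5, seed = 1),
               matrix(1L, 5, 1))
  expect_identical(draw_bootstrap_indices(10, 20, seed = 3),
                   draw_bootstrap_indices(10, 20, seed = 3))
  # expected distinct fraction 1 - (1 - 1/N)^N ~ 0.632 at N = 70
  idx <- draw_bootstrap_indices(70, 1000, seed = 4)
  frac <- mean(apply(idx, 1, function(r) length(unique(r)) / 70))
  expect_lt(abs(frac - (1 - (1 - 1 / 70)^70)), 0.03)
  # index draws are prefix-stable in B (checkpoint resumption relies on it)
  expect_identical(draw_bootstrap_indices(10, 4, seed = 5),
                   draw_bootstrap_indices(10, 8, seed = 5)[1:4, ])
})

test_that("selection frequencies are fractions of surviving bootstrap networks", {
  ts <- random_ts(4, 9, 2, seed = 6)
  pm <- permute_profiles(ts, seed = 7)
  idx1 <- draw_bootstrap_indices(build_design(ts, "g1", 2)$N, 1, seed = 8)
  one <- selection_frequencies(ts, pm, idx1, lambda = 0.01, a = 0.5)
  f <- one$frequencies[!is.na(one$frequencies)]
  expect_true(all(f %in% c(0, 1))) # B = 1
  # all-zero frequency when the data carry no signal at a harsh penalty
  expect_true(all(f >= 0 & f <= 1))
})

test_that("a strongly planted edge outranks non-edges in selection frequency", {
  sim <- simulate_var(p = 6, density = 0, n_times = 21, n_reps = 3,
                      noise_sd = 0.1, seed = 9)
  # plant one edge by hand: g1 -> g2 with coefficient 0.8 at lag 1
  coefs <- sim$coefficients
  coefs["g1", "g2", 1] <- 0.8
  vals <- array(0, c(6, 21, 3))
  set.seed(10)
  for (r in 1:3) vals[, , r] <- stabvar:::iterate_var(coefs, 21, 0.1, 200)
  ts <- center_profiles(expression_ts(vals, genes = dimnames(coefs)[[1]]))
  pm <- permute_profiles(ts, seed = 11)
  idx <- draw_bootstrap_indices(build_design(ts, "g1", 2)$N, 60, seed = 12)
  sf <- selection_frequencies(ts, pm, idx, lambda = 0.01, a = 0.5)
  pi_star <- sf$frequencies[, , 1]
  planted <- pi_star["g1", "g2"]
  others <- pi_star[!is.na(pi_star)]
  others <- others[-which(others == planted)[1]]
  expect_gt(planted, median(others))
})

test_that("the full pipeline is deterministic given its seed", {
  sim <- simulate_var(p = 5, density = 0.15, n_times = 12, n_reps = 3, seed = 13)
  f1 <- stabvar(sim$ts, boots = 20, seed = 14, lambda = 0.01, a = 0.5)
  f2 <- stabvar(sim$ts, boots = 20, seed = 14, lambda = 0.01, a = 0.5)
  expect_identical(f1$network, f2$network)
  expect_identical(f1$frequencies, f2$frequencies)
  expect_identical(f1$null_frequencies, f2$null_frequencies)
})

test_that("worker count does not change the result", {
  ts <- random_ts(4, 9, 2, seed = 15)
  pm <- permute_profiles(ts, seed = 16)
  idx <- draw_bootstrap_indices(build_design(ts, "g1", 2)$N, 10, seed = 17)
  a1 <- selection_frequencies(ts, pm, idx, 0.01, 0.5, cores = 1L)
  a2 <- selection_frequencies(ts, pm, idx, 0.01, 0.5, cores = 2L)
  expect_equal(a1, a2)
})

test_that("bootstrap checkpoints resume exactly", {
  ts <- random_ts(4, 9, 2, seed = 18)
  pm <- permute_profiles(ts, seed = 19)
  N <- build_design(ts, "g1", 2)$N
  idx <- draw_bootstrap_indices(N, 12, seed = 20)
  ck <- withr::local_tempfile(fileext = ".rds")
  full <- selection_frequencies(ts, pm, idx, 0.01, 0.5, checkpoint = ck)
  expect_true(file.exists(ck))
  # a second call with the checkpoint present skips all genes yet agrees
  again <- selection_frequencies(ts, pm, idx, 0.01, 0.5, checkpoint = ck)
  expect_equal(again, full)
  # a mismatched configuration invalidates the checkpoint instead of reusing it
  k1 <- readRDS(ck)$key
  selection_frequencies(ts, pm, idx, 0.02, 0.5, checkpoint = ck)
  expect_false(isTRUE(all.equal(readRDS(ck)$key, k1)))
})

test_that("lag choice takes the larger mean coefficient, ties to lag 1", {
  mc <- array(NA_real_, c(2, 2, 2))
  mc[1, 2, ] <- c(0.3, -0.1)  # lag 1 wins on magnitude
  mc[2, 1, ] <- c(0.2, -0.2)  # exact tie -> lag 1
  lc <- choose_lag(mc)
  expect_equal(lc[1, 2], 1L)
  expect_equal(lc[2, 1], 1L)
  expect_true(is.na(lc[1, 1]))
  # L = 1 degenerates to lag 1 everywhere
  lc1 <- choose_lag(array(rnorm(4), c(2, 2, 1)))
  expect_equal(lc1[1, 2], 1L)
})

test_that("network assembly applies the strict frequency cutoff and signs", {
  gs <- c("a", "b", "c")
  freq <- array(NA_real_, c(3, 3, 2), dimnames = list(gs, gs, NULL))
  mc <- freq
  freq[1, 2, ] <- c(0.9, 0.1); mc[1, 2, ] <- c(-0.5, 0.1)
  freq[2, 3, ] <- c(0.3, 0.6); mc[2, 3, ] <- c(0.1, 0.4)
  lc <- choose_lag(mc)
  net <- assemble_network(freq, mc, lc, threshold = 0.5)
  expect_equal(net$cause, c("a", "b"))
  expect_equal(net$sign, c(-1, 1))
  expect_equal(net$lag, c(1L, 2L))
  expect_equal(net$selection_frequency, c(0.9, 0.6))
  empty <- assemble_network(freq, mc, lc, threshold = 1)
  expect_equal(nrow(empty), 0L)
  all_in <- assemble_network(freq, mc, lc, threshold = 0)
  expect_true(all(all_in$sign == sign(all_in$effect_size)))
})

test_that("null stability run requires independent permutations and matches the real one under pure noise", {
  ts <- random_ts(10, 9, 2, seed = 21)
  pm1 <- permute_profiles(ts, seed = 22)
  pm2 <- permute_profiles(ts, seed = 23)
  idx <- draw_bootstrap_indices(build_design(ts, "g1", 2)$N, 100, seed = 24)
  expect_error(null_selection_frequencies(pm1, pm1, idx, 0.01, 0.5), "independent")
  real <- selection_frequencies(ts, pm1, idx, 0.01, 0.5)
  null <- null_selection_frequencies(pm2, pm1, idx, 0.01, 0.5)
  pr <- real$frequencies[!is.na(real$frequencies)]
  pn <- null$frequencies[!is.na(null$frequencies)]
  expect_gt(suppressWarnings(ks.test(pr, pn)$p.value), 0.01)
})
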