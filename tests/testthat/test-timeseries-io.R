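test_that("long TSV parsing builds the full series and flags missing entries", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ttime\treplicate\tvalue",
               "g1\t0\tr1\t1.5", "g1\t1\tr1\t2.5", "g1\t2\tr1\t3.5",
               "g2\t0\tr1\t-1", "g2\t1\tr1\t0"), f) # g2 at t=2 absent
  ts <- read_timeseries(f)
  expect_equal(dim(ts), c(2L, 3L, 1L))
  expect_equal(ts$values["g1", , "r1"], c(`0` = 1.5, `1` = 2.5, `2` = 3.5))
  expect_true(is.na(ts$values["g2", "2", "r1"]))
  expect_true(ts$missing["g2", "2", "r1"])
  expect_false(any(ts$missing["g1", , ]))
})

test_that("malformed long input is rejected with a useful message", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ttime\treplicate\tvalue",
               "g1\t0.5\trep1\t1", "g1\t0.5\trep1\t2"), f)
  expect_error(read_timeseries(f), "g1, 0.5, rep1")
  writeLines(c("gene\ttime\treplicate\tvalue",
               "g1\t0\tr1\t1", "g1\t1\tr1\tbogus"), f)
  expect_error(read_timeseries(f), "row 2")
})

test_that("wide layout round-trips a 12-time, 7-replicate series", {
  set.seed(41)
  times <- c(0, 0.5, 1, 2, 3, 4, 5, 6, 7, 8, 10, 12)
  reps <- paste0("r", 1:7)
  vals <- array(round(rnorm(3 * 12 * 7), 6), c(3, 12, 7))
  hdr <- paste(outer(times, reps, paste, sep = ":"))
  rows <- vapply(1:3, function(g)
    paste(c(paste0("g", g), as.vector(vals[g, , ])), collapse = "\t"), "")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(c("gene", hdr), collapse = "\t"), rows), f)
  ts <- read_timeseries(f, layout = "wide")
  expect_equal(dim(ts), c(3L, 12L, 7L))
  expect_equal(ts$times, times)
  expect_equal(unname(ts$values[2, , ]), vals[2, , ])
})

test_that("write then read reproduces values to 1e-12 and preserves the mask", {
  set.seed(7)
  arr <- array(rnorm(4 * 5 * 2), c(4, 5, 2))
  arr[2, 3, 1] <- NA
  ts <- expression_ts(arr, times = c(0, 0.5, 1, 2, 4))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_timeseries(ts, f)
  back <- read_timeseries(f)
  expect_equal(back$values, ts$values, tolerance = 1e-12)
  expect_equal(back$missing, ts$missing)
  expect_equal(back$times, ts$times)
})

test_that("centering subtracts per-profile means and nothing else", {
  ts <- tiny_ts(array(c(1, 5, 2, 5, 3, 5), c(2, 3, 1)))
  ct <- center_profiles(ts)
  expect_equal(unname(ct$values[1, , 1]), c(-1, 0, 1))
  expect_equal(unname(ct$values[2, , 1]), c(0, 0, 0)) # constant profile
  # variance untouched (no unit-variance rescale), all profile means ~0
  set.seed(2)
  ts2 <- tiny_ts(array(rnorm(3 * 6 * 2, sd = 2), c(3, 6, 2)))
  ct2 <- center_profiles(ts2)
  v_before <- apply(ts2$values, c(1, 3), var)
  v_after <- apply(ct2$values, c(1, 3), var)
  expect_equal(v_after, v_before, tolerance = 1e-12)
  expect_true(all(abs(apply(ct2$values, c(1, 3), mean)) < 1e-9))
  # idempotent
  expect_equal(center_profiles(ct2)$values, ct2$values, tolerance = 1e-14)
})

test_that("centering refuses incomplete series", {
  arr <- array(1:6, c(2, 3, 1)); arr[1, 2, 1] <- NA
  expect_error(center_profiles(expression_ts(arr)), "interpolate_missing")
})

test_that("interpolation is linear in real time, not index position", {
  arr <- array(NA_real_, c(1, 3, 1))
  arr[1, , 1] <- c(2, NA, 8)
  ts <- expression_ts(arr, times = c(4, 5, 7))
  out <- interpolate_missing(ts)
  expect_equal(unname(out$values[1, 2, 1]), 4) # 2 + 6*(5-4)/(7-4)
  # consecutive gaps share one segment
  arr2 <- array(NA_real_, c(1, 4, 1))
  arr2[1, , 1] <- c(1, NA, NA, 10)
  out2 <- interpolate_missing(expression_ts(arr2, times = c(4, 5, 6, 7)))
  expect_equal(unname(out2$values[1, , 1]), 1 + (10 - 1) * (c(4, 5, 6, 7) - 4) / 3)
  # no extrapolation
  arr3 <- array(c(1, 2, NA), c(1, 3, 1))
  expect_error(interpolate_missing(expression_ts(arr3)), "terminal")
  # complete data pass through untouched
  ts4 <- random_ts(2, 4, 2, seed = 9)
  expect_equal(interpolate_missing(ts4)$values, ts4$values)
})

test_that("profile permutation preserves per-profile multisets and seeds reproduce", {
  ts <- random_ts(4, 6, 3, seed = 11)
  pm <- permute_profiles(ts, seed = 5)
  for (g in 1:4) for (r in 1:3)
    expect_equal(sort(unname(pm$values[g, , r])),
                 sort(unname(ts$values[g, , r])))
  expect_equal(permute_profiles(ts, seed = 5)$values, pm$values)
  expect_false(identical(permute_profiles(ts, seed = 6)$values, pm$values))
  # single time point: nothing to shuffle
  one <- expression_ts(array(rnorm(3), c(3, 1, 1)))
  expect_equal(permute_profiles(one, seed = 1)$values, one$values)
})

test_that("zero-variance genes are dropped with a warning", {
  arr <- array(rnorm(9), c(3, 3, 1))
  arr[2, , 1] <- 7
  ts <- expression_ts(arr, genes = c("a", "flat", "c"))
  expect_warning(out <- drop_constant_genes(ts), "flat")
  expect_equal(dim(out)[1], 2L)
})

test_that("gene-class files read one label per line", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("TP53", "STAT1", "", "TP53"), f)
  cls <- read_gene_class(f, "tf")
  expect_equal(cls$class_name, "tf")
  expect_equal(cls$members, c("TP53", "STAT1"))
})
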