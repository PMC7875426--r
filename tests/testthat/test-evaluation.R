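make_gold <- function(edges, universe) {
  gold_standard(data.frame(cause = edges[, 1], effect = edges[, 2],
                           stringsAsFactors = FALSE), universe = universe)
}

test_that("AUPR matches exhaustive enumeration on small rankings", {
  gold <- make_gold(rbind(c("a", "b"), c("c", "d")), letters[1:4])
  # perfect ranking over the 2 true edges, rest unranked
  perfect <- data.frame(cause = c("a", "c"), effect = c("b", "d"))
  expect_equal(aupr(perfect, gold), 1.0)
  # truths at ranks 1 and 3 of a 4-candidate ranking
  ranked <- data.frame(cause = c("a", "b", "c", "d"),
                       effect = c("b", "a", "d", "c"))
  # candidates outside the ranking exist; restrict by scoring them below
  expect_equal(aupr(ranked, gold),
               ap_enumeration(c(TRUE, FALSE, TRUE, FALSE,
                                rep(FALSE, 8))), tolerance = 1e-12)
  expect_equal(aupr(ranked, gold), (1 / 1 + 2 / 3) / 2, tolerance = 1e-12)
})

test_that("reversed ranking at prevalence 1/2 gives AUPR 1/2", {
  gold <- make_gold(rbind(c("a", "b")), c("a", "b"))
  # candidate universe = {a->b, b->a}; rank the false edge first
  rev_rank <- data.frame(cause = c("b", "a"), effect = c("a", "b"))
  expect_equal(aupr(rev_rank, gold), 0.5)
  expect_equal(auroc(rev_rank, gold), 0)
})

test_that("AUROC equals the Mann-Whitney statistic, midranks under ties", {
  set.seed(1)
  u <- paste0("g", 1:5) # 20 candidate pairs
  pairs <- expand.grid(cause = u, effect = u, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$cause != pairs$effect, ]
  truth <- sample(c(TRUE, FALSE), 20, replace = TRUE, prob = c(0.3, 0.7))
  gold <- make_gold(as.matrix(pairs[truth, ]), u)
  scores <- round(rnorm(20), 1) # coarse: forces ties
  ranked <- data.frame(pairs, score = scores)
  w <- wilcox.test(scores[truth], scores[!truth], exact = FALSE)$statistic
  expect_equal(auroc(ranked, gold),
               unname(w) / (sum(truth) * sum(!truth)), tolerance = 1e-12)
  expect_equal(auroc(ranked[order(-ranked$score), ], gold),
               auroc(ranked, gold))
})

test_that("both metrics are invariant to monotone score transforms", {
  set.seed(2)
  u <- paste0("g", 1:4)
  pairs <- expand.grid(cause = u, effect = u, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$cause != pairs$effect, ]
  gold <- make_gold(as.matrix(pairs[c(1, 5, 8), ]), u)
  ranked <- data.frame(pairs, score = runif(12))
  warped <- transform(ranked, score = exp(3 * score) + 1)
  expect_equal(aupr(ranked, gold), aupr(warped, gold))
  expect_equal(auroc(ranked, gold), auroc(warped, gold))
})

test_that("degenerate rankings and gold standards are rejected", {
  gold <- make_gold(rbind(c("a", "b")), c("a", "b", "c"))
  expect_error(aupr(data.frame(cause = c("a", "a"), effect = c("b", "b")), gold),
               "duplicate")
  expect_error(aupr(data.frame(cause = "z", effect = "a"), gold), "universe")
  empty <- gold_standard(data.frame(cause = character(), effect = character()),
                         universe = c("a", "b"))
  expect_error(aupr(data.frame(cause = "a", effect = "b"), empty), "empty gold")
  expect_error(gold_standard(data.frame(cause = "a", effect = "a")), "self")
})

test_that("gold-standard files round-trip and malformed lines are located", {
  gold <- make_gold(rbind(c("g1", "g2"), c("g2", "g3")), paste0("g", 1:3))
  gold$negatives <- data.frame(cause = "g3", effect = "g1",
                               stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_gold_standard(gold, f)
  back <- read_gold_standard(f)
  expect_equal(back$true_edges, gold$true_edges, ignore_attr = TRUE)
  expect_equal(nrow(back$negatives), 1L)
  writeLines(c("g1\tg2\t1", "g1\tg3"), f)
  expect_error(read_gold_standard(f), "line 2")
  writeLines(c("g1\tg2\t0", "g2\tg3\t0"), f)
  onlyneg <- read_gold_standard(f)
  expect_equal(nrow(onlyneg$true_edges), 0L)
  expect_error(aupr(data.frame(cause = "g1", effect = "g2"), onlyneg),
               "empty gold")
})

test_that("random rankings concentrate at AUROC 1/2 and AUPR near prevalence", {
  set.seed(3)
  u <- paste0("g", 1:6)
  pairs <- expand.grid(cause = u, effect = u, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$cause != pairs$effect, ]
  truth <- seq_len(nrow(pairs)) %in% sample(nrow(pairs), 9)
  gold <- make_gold(as.matrix(pairs[truth, ]), u)
  rho <- mean(truth)
  ap <- roc <- numeric(200)
  for (k in 1:200) {
    ranked <- data.frame(pairs[sample(nrow(pairs)), ], score = seq(1, 0, length.out = 30))
    ap[k] <- aupr(ranked, gold)
    roc[k] <- auroc(ranked, gold)
  }
  expect_lt(abs(mean(roc) - 0.5), 3 * sd(roc) / sqrt(200) + 0.005)
  # exact finite-sample expectation of average precision under a uniformly
  # random ranking, from the negative-hypergeometric rank distribution
  n <- nrow(pairs); P <- sum(truth)
  e_ap <- mean(vapply(1:P, function(k) {
    r <- k:(n - P + k)
    sum(k / r * choose(r - 1, k - 1) * choose(n - r, P - k)) / choose(n, P)
  }, 0))
  expect_lt(abs(mean(ap) - e_ap), 3 * sd(ap) / sqrt(200) + 0.005)
  # the finite-sample expectation sits above and near the prevalence,
  # approaching it as the candidate set grows
  expect_gte(e_ap, rho)
  expect_lt(e_ap - rho, 0.1)
})

test_that("enrichment tables reproduce published-scale odds ratios from raw counts", {
  tf <- class_enrichment(2768, 226, 466, 62)
  expect_equal(signif(tf$odds_ratio, 2), 2.0)
  imm <- class_enrichment(2768, 109, 466, 39)
  expect_equal(signif(imm$odds_ratio, 2), 2.9)
  met <- class_enrichment(2768, 120, 466, 19)
  expect_equal(signif(met$odds_ratio, 2), 0.93)
  expect_lt(tf$p_value, 1e-4)
  expect_gt(met$p_value, 0.5)
})

test_that("enrichment arithmetic and error handling are sound", {
  # overlap at its independence expectation gives OR ~ 1
  et <- class_enrichment(1000, 100, 200, 20)
  expect_equal(et$odds_ratio, 1, tolerance = 0.05)
  expect_equal(et$a + et$b + et$c + et$d, 1000)
  inf <- class_enrichment(100, 10, 10, 10)
  expect_equal(inf$odds_ratio, Inf)
  expect_error(class_enrichment(100, 10, 20, 15), "overlap")
  expect_error(class_enrichment(100, 90, 90, 5), "inconsistent")
})

test_that("batch enrichment BH adjustment preserves p-value order", {
  set.seed(4)
  universe <- paste0("g", 1:300)
  classes <- list(a = sample(universe, 40), b = sample(universe, 25),
                  c = sample(universe, 60), d = sample(universe, 10))
  selected <- sample(universe, 80)
  out <- enrichment_tests(universe, selected, classes)
  expect_equal(nrow(out), 4L)
  expect_true(all(diff(out$p_adj[order(out$p)]) >= -1e-12))
  expect_true(all(out$p_adj >= out$p - 1e-12))
})
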