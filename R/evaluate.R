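#' Gold-standard directed edge set
#'
#' @param true_edges data frame with columns `cause`, `effect` (ordered
#'   pairs, no self edges).
#' @param universe ordered gene labels; defaults to the genes appearing in
#'   `true_edges`.
#' @param negatives optional data frame of explicitly declared non-edges.
#' @return Object of class `gold_standard`.
#' @export
gold_standard <- function(true_edges, universe = NULL, negatives = NULL) {
  true_edges <- as.data.frame(true_edges, stringsAsFactors = FALSE)
  if (!all(c("cause", "effect") %in% names(true_edges)))
    stop_("true_edges needs columns cause, effect")
  if (any(true_edges$cause == true_edges$effect))
    stop_("gold standard contains self edges")
  if (is.null(universe))
    universe <- sort(unique(c(true_edges$cause, true_edges$effect)))
  if (!all(c(true_edges$cause, true_edges$effect) %in% universe))
    stop_("true edges mention genes outside the universe")
  key <- paste(true_edges$cause, true_edges$effect, sep = "\r")
  if (anyDuplicated(key)) stop_("duplicated gold-standard edge")
  structure(list(universe = universe,
                 true_edges = true_edges[c("cause", "effect")],
                 negatives = negatives),
            class = "gold_standard")
}

#' @export
print.gold_standard <- function(x, ...) {
  cat(sprintf("gold_standard: %d genes, %d true directed edges\n",
              length(x$universe), nrow(x$true_edges)))
  invisible(x)
}

#' Read / write a gold standard in the three-column benchmark dialect
#'
#' Tab-separated lines `cause<TAB>effect<TAB>{0|1}`, no header.  Flag-1
#' lines are true edges; flag-0 lines are recorded as explicit negatives.
#'
#' @param path file path.
#' @param universe optional gene universe; defaults to genes in the file.
#' @return A [gold_standard()].
#' @export
read_gold_standard <- function(path, universe = NULL) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  parts <- strsplit(ln, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad)) stop_("malformed gold-standard line ", bad[1])
  m <- do.call(rbind, parts)
  flag <- m[, 3]
  if (!all(flag %in% c("0", "1"))) {
    stop_("malformed gold-standard line ", which(!flag %in% c("0", "1"))[1],
          ": flag must be 0 or 1")
  }
  df <- data.frame(cause = m[, 1], effect = m[, 2], stringsAsFactors = FALSE)
  gold_standard(df[flag == "1", , drop = FALSE],
                universe = universe %||% sort(unique(c(m[, 1], m[, 2]))),
                negatives = df[flag == "0", , drop = FALSE])
}

#' @rdname read_gold_standard
#' @param gold a [gold_standard()].
#' @export
write_gold_standard <- function(gold, path) {
  pos <- cbind(gold$true_edges, flag = 1L)
  neg <- if (!is.null(gold$negatives) && nrow(gold$negatives))
    cbind(gold$negatives[c("cause", "effect")], flag = 0L)
  write.table(rbind(pos, neg), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Expand a ranking into scores over the full candidate universe (all
# ordered non-self pairs).  Ranked edges score by descending position (or
# an explicit score column); unranked candidates are appended as
# non-predictions, tied at -Inf.
candidate_scores <- function(ranked, gold) {
  if (nrow(gold$true_edges) == 0L) stop_("empty gold standard")
  u <- gold$universe
  cand <- expand.grid(cause = u, effect = u, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  cand <- cand[cand$cause != cand$effect, ]
  key <- function(d) paste(d$cause, d$effect, sep = "\r")
  ck <- key(cand)
  ranked <- as.data.frame(ranked, stringsAsFactors = FALSE)
  rk <- key(ranked)
  if (anyDuplicated(rk)) stop_("ranking contains duplicate edges")
  if (!all(rk %in% ck)) {
    stop_("ranked edges outside the candidate universe: ",
          paste(head(setdiff(c(ranked$cause, ranked$effect), u), 5), collapse = ", "))
  }
  score <- rep(-Inf, nrow(cand))
  pos <- match(rk, ck)
  score[pos] <- if ("score" %in% names(ranked)) ranked$score
                else rev(seq_len(nrow(ranked)))
  list(score = score, truth = ck %in% key(gold$true_edges),
       cause = cand$cause, effect = cand$effect)
}

#' Area under the precision-recall curve of a ranked edge list
#'
#' Sweeps the inclusion threshold down the ranking and accumulates the
#' step-curve (average-precision) area, the conservative convention for
#' sparse networks: no interpolation between PR points.  Candidate edges
#' not present in the ranking are appended as non-predictions, so the curve
#' bottoms out at the prevalence.  Score ties (and all unranked candidates)
#' are ordered lexicographically by (cause, effect) for the sweep.
#'
#' @param ranked data frame with columns `cause`, `effect` in rank order
#'   (best first); an optional `score` column overrides rank order.
#' @param gold a [gold_standard()].
#' @return AUPR in `[0, 1]`.
#' @export
aupr <- function(ranked, gold) {
  cs <- candidate_scores(ranked, gold)
  ord <- order(-cs$score, cs$cause, cs$effect)
  truth <- cs$truth[ord]
  P <- sum(truth)
  hits <- which(truth)
  sum(seq_along(hits) / hits) / P
}

#' Area under the ROC curve of a ranked edge list
#'
#' Equals the Mann-Whitney probability that a uniformly chosen true edge
#' outranks a uniformly chosen non-edge; ties in score (including all
#' unranked candidates) contribute 1/2 via midranks.
#'
#' @inheritParams aupr
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(ranked, gold) {
  cs <- candidate_scores(ranked, gold)
  r <- rank(cs$score) # midranks for ties
  n1 <- sum(cs$truth)
  n0 <- length(r) - n1
  (sum(r[cs$truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Gene-class enrichment contingency table
#'
#' Builds the 2x2 table for enrichment of a gene class among a selected
#' gene set drawn from a common universe, reporting the sample odds ratio
#' `(a*d)/(b*c)` (which reproduces the printed enrichment values) alongside
#' the two-sided Fisher exact p-value (whose internal estimate is the
#' conditional-ML odds ratio).
#'
#' @param universe_size number of genes in the universe.
#' @param class_size number of universe genes in the class.
#' @param selected_size number of selected genes.
#' @param overlap number of selected genes in the class.
#' @return Object of class `enrichment_table`: list with cells `a` (class
#'   and selected), `b` (selected only), `c` (class only), `d` (neither),
#'   `odds_ratio`, and `p_value`.
#' @export
#' @examples
#' class_enrichment(2768, 226, 466, 62)$odds_ratio # ~2.0
class_enrichment <- function(universe_size, class_size, selected_size, overlap) {
  cells <- c(universe_size, class_size, selected_size, overlap)
  if (any(cells != round(cells)) || any(cells < 0))
    stop_("counts must be non-negative integers")
  if (overlap > min(class_size, selected_size))
    stop_("overlap exceeds class or selection size")
  a <- overlap
  b <- selected_size - overlap
  c_ <- class_size - overlap
  d <- universe_size - selected_size - c_
  if (d < 0) stop_("counts inconsistent with the universe size")
  or <- if (b * c_ == 0) {
    if (a * d > 0) Inf else NaN
  } else (a * d) / (b * c_)
  p <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))$p.value
  structure(list(a = a, b = b, c = c_, d = d, odds_ratio = or, p_value = p),
            class = "enrichment_table")
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat(sprintf("enrichment 2x2: a=%d b=%d c=%d d=%d  OR=%.3g  p=%.3g\n",
              x$a, x$b, x$c, x$d, x$odds_ratio, x$p_value))
  invisible(x)
}

#' Batch gene-class enrichment with multiple-testing adjustment
#'
#' Runs [class_enrichment()] for each class against a selected gene set and
#' adjusts the Fisher p-values across classes by Benjamini-Hochberg.
#'
#' @param universe character vector of all genes.
#' @param selected character vector of selected genes (subset of universe).
#' @param classes named list of character vectors (one gene class each);
#'   members outside the universe are ignored.
#' @return Data frame with one row per class: cells, sample odds ratio,
#'   raw and BH-adjusted p-values.
#' @export
enrichment_tests <- function(universe, selected, classes) {
  if (!all(selected %in% universe)) stop_("selected genes outside the universe")
  rows <- lapply(names(classes), function(nm) {
    cls <- intersect(classes[[nm]], universe)
    et <- class_enrichment(length(universe), length(cls), length(selected),
                           length(intersect(cls, selected)))
    data.frame(class = nm, a = et$a, b = et$b, c = et$c, d = et$d,
               odds_ratio = et$odds_ratio, p = et$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out
}
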