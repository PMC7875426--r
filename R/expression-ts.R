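#' Replicated expression time series
#'
#' Container for gene expression measured over time in one or more
#' replicates.  Values are held as a 3-dimensional array indexed by gene,
#' time point and replicate, together with the real-valued sampling times
#' and a mask recording which entries were missing in the source data
#' (missing values are `NA` in `values` until [interpolate_missing()] fills
#' them).
#'
#' @param values numeric array of dimension `p x T x R` (genes, time points,
#'   replicates).  A matrix is treated as a single replicate.
#' @param times strictly increasing numeric vector of sampling times,
#'   length `T`.  Defaults to `1:T`.
#' @param genes,replicates optional labels; taken from `dimnames(values)`
#'   when present, otherwise generated (`g1, g2, ...` / `r1, r2, ...`).
#' @param missing optional logical array of the same dimension marking
#'   originally-missing entries; defaults to `is.na(values)`.
#' @return An object of class `expression_ts`.
#' @seealso [read_timeseries()], [center_profiles()], [interpolate_missing()]
#' @export
#' @examples
#' x <- array(rnorm(2 * 5 * 3), c(2, 5, 3))
#' ts <- expression_ts(x, times = c(0, 0.5, 1, 2, 4))
#' ts
expression_ts <- function(values, times = NULL, genes = NULL,
                          replicates = NULL, missing = NULL) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L),
                                         dimnames = c(dimnames(values), list(NULL)))
  if (!is.array(values) || length(dim(values)) != 3L || !is.numeric(values))
    stop_("values must be a numeric gene x time x replicate array")
  d <- dim(values)
  if (is.null(genes)) genes <- dimnames(values)[[1]]
  if (is.null(genes)) genes <- paste0("g", seq_len(d[1]))
  if (anyDuplicated(genes)) stop_("gene labels must be unique")
  if (is.null(replicates)) replicates <- dimnames(values)[[3]]
  if (is.null(replicates)) replicates <- paste0("r", seq_len(d[3]))
  if (anyDuplicated(replicates)) stop_("replicate labels must be unique")
  if (is.null(times)) times <- seq_len(d[2])
  times <- as.numeric(times)
  if (length(times) != d[2] || anyNA(times) || any(diff(times) <= 0))
    stop_("times must be strictly increasing and match the time dimension")
  if (is.null(missing)) missing <- is.na(values)
  missing <- array(as.logical(missing), d)
  if (any(is.na(values) & !missing))
    stop_("values contains NA entries not covered by the missing mask")
  dimnames(values) <- dimnames(missing) <-
    list(gene = genes, time = as.character(times), replicate = replicates)
  structure(list(values = values, times = times, missing = missing),
            class = "expression_ts")
}

genes.expression_ts <- function(ts) dimnames(ts$values)[[1]]
reps.expression_ts <- function(ts) dimnames(ts$values)[[3]]

#' @export
print.expression_ts <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("expression_ts: %d genes x %d time points x %d replicate%s\n",
              d[1], d[2], d[3], if (d[3] == 1) "" else "s"))
  cat(sprintf("  times: %s\n", paste(format(x$times, trim = TRUE), collapse = " ")))
  nm <- sum(x$missing & is.na(x$values))
  if (nm) cat(sprintf("  %d missing entr%s (run interpolate_missing())\n",
                      nm, if (nm == 1) "y" else "ies"))
  invisible(x)
}

#' @export
dim.expression_ts <- function(x) dim(x$values)

#' @export
as.data.frame.expression_ts <- function(x, ...) {
  d <- dim(x$values)
  df <- data.frame(
    gene = rep(genes.expression_ts(x), times = d[2] * d[3]),
    time = rep(rep(x$times, each = d[1]), times = d[3]),
    replicate = rep(reps.expression_ts(x), each = d[1] * d[2]),
    value = as.vector(x$values),
    stringsAsFactors = FALSE
  )
  df[!as.vector(x$missing), , drop = FALSE]
}

is_complete <- function(ts) !any(is.na(ts$values))

#' Read an expression time series from a TSV file
#'
#' The canonical `long` layout is a tab-separated file with a header and
#' columns `gene`, `time`, `replicate`, `value` (one row per observation).
#' The `wide` convenience layout has one row per gene: a first column
#' `gene`, then one column per (time, replicate) sample whose header is
#' `<time>:<replicate>`, e.g. `0.5:r1`.
#'
#' Any (gene, time, replicate) combination absent from the file is recorded
#' as missing, never silently zero-filled.  Duplicated triples and
#' non-numeric values are hard errors.
#'
#' @param path file path.
#' @param layout `"long"` (default) or `"wide"`.
#' @return An [expression_ts()] object.
#' @export
read_timeseries <- function(path, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  if (layout == "wide") return(read_timeseries_wide(path))
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character", check.names = FALSE)
  need <- c("gene", "time", "replicate", "value")
  if (!all(need %in% names(df)))
    stop_("long layout requires columns: ", paste(need, collapse = ", "))
  val <- suppressWarnings(as.numeric(df$value))
  bad <- which(is.na(val) & !(df$value %in% c("NA", "")))
  if (length(bad))
    stop_("non-numeric value at row ", bad[1], ": '", df$value[bad[1]], "'")
  tm <- suppressWarnings(as.numeric(df$time))
  if (anyNA(tm)) stop_("non-numeric time at row ", which(is.na(tm))[1])
  key <- paste(df$gene, tm, df$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    d1 <- df[which(duplicated(key))[1], ]
    stop_(sprintf("duplicated (gene, time, replicate) triple: (%s, %s, %s)",
                  d1$gene, d1$time, d1$replicate))
  }
  genes <- unique(df$gene)
  times <- sort(unique(tm))
  reps <- unique(df$replicate)
  arr <- array(NA_real_, c(length(genes), length(times), length(reps)))
  idx <- cbind(match(df$gene, genes), match(tm, times), match(df$replicate, reps))
  arr[idx] <- val
  expression_ts(arr, times = times, genes = genes, replicates = reps)
}

read_timeseries_wide <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character", check.names = FALSE)
  if (names(df)[1] != "gene") stop_("wide layout requires first column 'gene'")
  if (anyDuplicated(df$gene)) stop_("duplicated gene row: ", df$gene[anyDuplicated(df$gene)])
  hdr <- names(df)[-1]
  parts <- strsplit(hdr, ":", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop_("wide sample headers must be '<time>:<replicate>'")
  htime <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
  if (anyNA(htime)) stop_("non-numeric time in wide header")
  hrep <- vapply(parts, `[`, "", 2L)
  if (anyDuplicated(paste(htime, hrep, sep = "\r")))
    stop_("duplicated (time, replicate) column in wide header")
  long <- data.frame(
    gene = rep(df$gene, times = length(hdr)),
    time = rep(htime, each = nrow(df)),
    replicate = rep(hrep, each = nrow(df)),
    value = unlist(df[-1], use.names = FALSE),
    stringsAsFactors = FALSE
  )
  val <- suppressWarnings(as.numeric(long$value))
  bad <- which(is.na(val) & !(long$value %in% c("NA", "")))
  if (length(bad)) stop_("non-numeric value at row ", bad[1])
  genes <- unique(long$gene)
  times <- sort(unique(long$time))
  reps <- unique(long$replicate)
  arr <- array(NA_real_, c(length(genes), length(times), length(reps)))
  arr[cbind(match(long$gene, genes), match(long$time, times),
            match(long$replicate, reps))] <- val
  expression_ts(arr, times = times, genes = genes, replicates = reps)
}

#' Write an expression time series as long TSV
#'
#' Missing entries are omitted from the file, so a write/read round trip
#' reproduces both the values and the missing mask.
#'
#' @param ts an [expression_ts()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  df <- as.data.frame(ts)
  df$value <- format(df$value, digits = 17, trim = TRUE, scientific = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Center every gene temporal profile to mean zero
#'
#' Subtracts, for each (gene, replicate) pair, the mean of that profile
#' across time.  Variances are deliberately left untouched: rescaling to
#' unit variance would inflate the apparent influence of genes with nearly
#' flat profiles.
#'
#' @param ts a complete [expression_ts()] (no missing entries).
#' @return The centered series.
#' @export
center_profiles <- function(ts) {
  if (!is_complete(ts))
    stop_("missing entries present; run interpolate_missing() first")
  mu <- apply(ts$values, c(1, 3), mean)
  ts$values <- ts$values - aperm(array(mu, dim(ts$values)[c(1, 3, 2)]), c(1, 3, 2))
  ts
}

#' Linearly interpolate missing time points
#'
#' Each missing value is filled by linear interpolation in actual time
#' coordinates between the nearest observed neighbours of the same
#' (gene, replicate) profile.  Missing values at the first or last time
#' point are an error: the method does not extrapolate.
#'
#' @param ts an [expression_ts()].
#' @return The completed series; the missing mask still records which
#'   entries were imputed.
#' @export
interpolate_missing <- function(ts) {
  d <- dim(ts$values)
  for (g in seq_len(d[1])) for (r in seq_len(d[3])) {
    y <- ts$values[g, , r]
    if (!anyNA(y)) next
    obs <- which(!is.na(y))
    if (is.na(y[1]) || is.na(y[d[2]]))
      stop_(sprintf("missing value at a terminal time point (gene %s, replicate %s); cannot extrapolate",
                    genes.expression_ts(ts)[g], reps.expression_ts(ts)[r]))
    ts$values[g, , r] <- approx(ts$times[obs], y[obs], xout = ts$times)$y
  }
  ts
}

#' Independently permute every gene temporal profile across time
#'
#' Used to build the permutation null for edge significance: shuffling each
#' (gene, replicate) profile over time destroys lagged dependence between
#' genes while preserving each profile's marginal distribution.
#' Permutations are drawn independently for every gene and replicate.
#'
#' @param ts a complete [expression_ts()].
#' @param seed integer seed; the same seed reproduces the same permutation.
#' @return A permuted [expression_ts()].
#' @export
permute_profiles <- function(ts, seed) {
  if (!is_complete(ts)) stop_("missing entries present; complete the series first")
  d <- dim(ts$values)
  with_seed(seed, {
    for (r in seq_len(d[3])) for (g in seq_len(d[1])) {
      ts$values[g, , r] <- ts$values[g, sample.int(d[2]), r]
    }
  })
  ts
}

#' Drop genes whose expression is constant across all samples
#'
#' Constant profiles carry no temporal signal and destabilise leave-one-out
#' cross-validation, so they are removed (with a warning) before fitting.
#'
#' @param ts an [expression_ts()].
#' @return The series restricted to non-constant genes.
#' @export
drop_constant_genes <- function(ts) {
  v <- apply(ts$values, 1, function(z) var(as.vector(z), na.rm = TRUE))
  flat <- which(v == 0 | is.na(v))
  if (length(flat)) {
    warning("dropping ", length(flat), " zero-variance gene(s): ",
            paste(genes.expression_ts(ts)[flat], collapse = ", "), call. = FALSE)
    ts$values <- ts$values[-flat, , , drop = FALSE]
    ts$missing <- ts$missing[-flat, , , drop = FALSE]
  }
  ts
}

#' Read a gene-class annotation file
#'
#' One gene label per line; blank lines ignored.
#'
#' @param path file path.
#' @param class_name optional class label; defaults to the file name.
#' @return A list with `class_name` and `members` (unique gene labels).
#' @export
read_gene_class <- function(path, class_name = NULL) {
  members <- readLines(path)
  members <- unique(members[nzchar(trimws(members))])
  list(class_name = class_name %||% sub("\\.[^.]*$", "", basename(path)),
       members = members)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
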