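#' Cosine similarity of two spectra
#'
#' Treats two spectra as vectors and returns the cosine of the angle between
#' them: `sum(a*b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))`. Identical directions
#' give 1, orthogonal vectors give 0; for non-negative (preprocessed) spectra
#' the value lies in \[0, 1\]. Scale-free: multiplying either vector by a
#' positive constant leaves the similarity unchanged.
#'
#' @param a,b Numeric vectors of equal length >= 1, neither all-zero.
#' @return Scalar cosine similarity in \[-1, 1\].
#' @export
cosine_similarity <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b) || length(a) < 1L)
    stop("cosine_similarity: vectors must have equal positive length",
         call. = FALSE)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("cosine_similarity: zero-norm vector (angle undefined)",
         call. = FALSE)
  sum(a * b) / (na * nb)
}

#' Mean reference spectrum of one leaf
#'
#' Channel-wise arithmetic mean over all spectra of a leaf; averaging damps
#' position-specific noise, so the mean serves as the reference each
#' position is compared against.
#'
#' @param set A (preprocessed) [spectrum_set()].
#' @param leaf_id Leaf identifier present in the set.
#' @return Numeric vector over the wavenumber axis.
#' @export
leaf_mean_spectrum <- function(set, leaf_id) {
  stopifnot(inherits(set, "spectrum_set"))
  rows <- which(set$meta$leaf_id == leaf_id)
  if (!length(rows))
    stop("leaf_mean_spectrum: unknown leaf_id '", leaf_id, "'", call. = FALSE)
  colMeans(set$intensities[rows, , drop = FALSE])
}

#' Per-position similarity to the leaf mean spectrum
#'
#' Scores every spectrum by its cosine similarity to its own leaf's mean
#' spectrum. Flag columns (`is_outlier`, `below_q1`) are initialised to `NA`
#' and filled by [boxplot_outliers()].
#'
#' @param set A preprocessed [spectrum_set()].
#' @return A `similarity_table`: data frame with one row per spectrum and
#'   columns `spectrum_id`, `leaf_id`, `group`, `duration_h`, `grid_row`,
#'   `grid_col`, `similarity`, `is_outlier`, `below_q1`.
#' @export
similarity_table <- function(set) {
  stopifnot(inherits(set, "spectrum_set"))
  sims <- numeric(n_spectra(set))
  for (lid in unique(set$meta$leaf_id)) {
    rows <- which(set$meta$leaf_id == lid)
    ref <- colMeans(set$intensities[rows, , drop = FALSE])
    for (i in rows)
      sims[i] <- cosine_similarity(set$intensities[i, ], ref)
  }
  out <- set$meta[, META_REQUIRED, drop = FALSE]
  out$similarity <- sims
  out$is_outlier <- NA
  out$below_q1 <- NA
  class(out) <- c("similarity_table", "data.frame")
  out
}

#' Flag box-plot outliers and below-quartile positions
#'
#' Classical box-plot rule on the similarity values: `is_outlier` marks
#' values below the lower whisker fence `Q1 - 1.5 * IQR`, `below_q1` marks
#' values strictly below the lower quartile. Quartiles use linear
#' interpolation of the empirical distribution (`stats::quantile` type 7).
#' The thresholds can be computed on the pooled population (`"all"`, the
#' single-box-plot convention) or separately per leaf (`"per_leaf"`, the
#' population the cleansing step uses).
#'
#' @param sims A [similarity_table()].
#' @param population `"all"` or `"per_leaf"`; each population needs >= 4
#'   values for a stable quartile.
#' @param qtype Quantile algorithm type passed to [stats::quantile()].
#' @return The table with flags filled; attribute `"summary"` holds per-
#'   population min, max, mean, sd, Q1 and the lower fence.
#' @export
boxplot_outliers <- function(sims, population = c("all", "per_leaf"),
                             qtype = 7) {
  population <- match.arg(population)
  stopifnot(inherits(sims, "similarity_table"))
  pop_of <- if (population == "all") rep("all", nrow(sims)) else sims$leaf_id

  summaries <- list()
  for (p in unique(pop_of)) {
    rows <- which(pop_of == p)
    x <- sims$similarity[rows]
    if (length(x) < 4L)
      stop("boxplot_outliers: population '", p, "' has fewer than 4 values",
           call. = FALSE)
    q1 <- unname(stats::quantile(x, 0.25, type = qtype))
    q3 <- unname(stats::quantile(x, 0.75, type = qtype))
    fence <- q1 - 1.5 * (q3 - q1)
    sims$is_outlier[rows] <- x < fence
    sims$below_q1[rows] <- x < q1
    summaries[[p]] <- data.frame(population = p, n = length(x),
                                 min = min(x), max = max(x),
                                 mean = mean(x), sd = stats::sd(x),
                                 q1 = q1, lower_fence = fence)
  }
  attr(sims, "summary") <- do.call(rbind, c(summaries,
                                            list(make.row.names = FALSE)))
  sims
}

#' Tabulate flagged spectra by group and stress duration
#'
#' @param sims A flagged [similarity_table()] (after [boxplot_outliers()]).
#' @param flag Which flag to count, `"is_outlier"` or `"below_q1"`.
#' @return Duration x group count matrix with margin totals
#'   (see [add_margin_totals()]); the corner cell is the grand total.
#' @export
tabulate_flags <- function(sims, flag = c("is_outlier", "below_q1")) {
  flag <- match.arg(flag)
  stopifnot(inherits(sims, "similarity_table"))
  f <- sims[[flag]]
  if (all(is.na(f)))
    stop("tabulate_flags: flags not set; run boxplot_outliers() first",
         call. = FALSE)
  keep <- sims[which(f), , drop = FALSE]
  tab <- table(duration_h = factor(keep$duration_h, DURATION_LEVELS),
               group = factor(keep$group, GROUP_LEVELS))
  add_margin_totals(unclass(tab))
}

#' Minimum similarity over growing prefixes of a replicate stream
#'
#' @param sims Numeric vector of per-replicate similarities in acquisition
#'   order.
#' @param counts Collection counts at which to take the running minimum.
#' @return Named numeric vector of minima, one per requested count (counts
#'   beyond the stream length are dropped with a warning).
#' @export
prefix_minima <- function(sims, counts = c(10L, 20L, 30L)) {
  counts <- sort(as.integer(counts))
  avail <- counts[counts <= length(sims)]
  if (length(avail) < length(counts))
    warning("prefix_minima: only ", length(sims),
            " replicates; restricting to counts ",
            paste(avail, collapse = ", "))
  if (!length(avail))
    stop("prefix_minima: no requested count is available", call. = FALSE)
  vapply(avail, function(k) min(sims[seq_len(k)]),
         numeric(1), USE.NAMES = FALSE) |>
    stats::setNames(as.character(avail))
}

#' Summarise per-position repeatability minima
#'
#' Cross-position means of the per-position minimum similarities at each
#' collection count, plus the comparison against a stability floor.
#'
#' @param minima Numeric matrix: rows = positions, columns = collection
#'   counts (column names = counts).
#' @param floor Reference stability benchmark (default 0.991). This is a
#'   reporting benchmark, not a hard filter.
#' @return List with `minima`, `means` (per count), `floor` and `all_above`
#'   (logical: every minimum >= floor).
#' @export
repeatability_summary <- function(minima, floor = 0.991) {
  minima <- as.matrix(minima)
  list(minima = minima,
       means = colMeans(minima),
       floor = floor,
       all_above = all(minima >= floor))
}

#' Repeatability report from replicate streams
#'
#' For each position, all replicates are compared (cosine) to the mean
#' spectrum over the full stream — a fixed reference, which makes the
#' per-position minimum non-increasing in the collection count — and the
#' running minima at the requested counts are tabulated across positions.
#'
#' @param streams Named list, one numeric matrix per position (rows =
#'   replicate spectra in acquisition order, columns = channels).
#' @param counts Collection counts at which minima are reported.
#' @param floor Stability benchmark, see [repeatability_summary()].
#' @return A `repeatability_report`: the [repeatability_summary()] list plus
#'   `counts` and per-position similarity vectors in `similarities`.
#' @export
repeatability_report <- function(streams, counts = c(10L, 20L, 30L),
                                 floor = 0.991) {
  stopifnot(is.list(streams), length(streams) >= 1L)
  if (is.null(names(streams)))
    names(streams) <- paste0("P", seq_along(streams))
  sims <- lapply(streams, function(m) {
    m <- as.matrix(m)
    ref <- colMeans(m)
    apply(m, 1L, cosine_similarity, b = ref)
  })
  counts <- sort(as.integer(counts))
  n_min <- min(vapply(sims, length, 1L))
  avail <- counts[counts <= n_min]
  if (!length(avail))
    stop("repeatability_report: shortest stream (", n_min,
         " replicates) is below every requested count", call. = FALSE)
  if (length(avail) < length(counts))
    warning("repeatability_report: fewer than ", max(counts),
            " replicates; restricting to counts ",
            paste(avail, collapse = ", "))
  minima <- do.call(rbind, lapply(sims, function(s) prefix_minima(s, avail)))
  colnames(minima) <- as.character(avail)
  out <- repeatability_summary(minima, floor)
  out$counts <- as.integer(colnames(out$minima))
  out$similarities <- sims
  class(out) <- "repeatability_report"
  out
}

#' @export
print.repeatability_report <- function(x, ...) {
  cat("<repeatability_report> ", nrow(x$minima), " position(s)\n", sep = "")
  print(round(x$minima, 5))
  cat("means:", paste(sprintf("%s=%.5f", names(x$means), x$means),
                      collapse = "  "), "\n")
  cat("stability floor ", x$floor, ": ",
      if (x$all_above) "all minima above" else "NOT all minima above",
      "\n", sep = "")
  invisible(x)
}
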