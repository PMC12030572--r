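#' Remove low-similarity spectra
#'
#' Excludes every spectrum whose similarity falls strictly below the lower
#' `q` quantile of its population (by default the lower quartile of its own
#' leaf). Ties at the threshold are kept — "below the quartile" is read
#' strictly. Leaves with fewer than 4 spectra are passed through uncleansed
#' with a warning, since their quartile is unstable.
#'
#' @param set The [spectrum_set()] the similarities were computed on.
#' @param sims A [similarity_table()] covering every spectrum of `set`.
#' @param q Lower quantile in (0, 1); default 0.25.
#' @param population `"per_leaf"` (default) or `"all"` (one pooled
#'   threshold).
#' @param qtype Quantile algorithm type passed to [stats::quantile()].
#' @return A `cleansing_result`: list with `kept` (a `spectrum_set`),
#'   `excluded_ids`, `rule` and `per_leaf` counts (`before`, `excluded`,
#'   `after`; `before = excluded + after` for every leaf).
#' @export
cleanse <- function(set, sims, q = 0.25,
                    population = c("per_leaf", "all"), qtype = 7) {
  population <- match.arg(population)
  stopifnot(inherits(set, "spectrum_set"), inherits(sims, "similarity_table"))
  if (!is.numeric(q) || q <= 0 || q >= 1)
    stop("cleanse: q must lie in (0, 1)", call. = FALSE)
  pos <- match(set$meta$spectrum_id, sims$spectrum_id)
  if (any(is.na(pos)))
    stop("cleanse: similarity table does not cover the set", call. = FALSE)
  sim <- sims$similarity[pos]

  excluded <- logical(n_spectra(set))
  if (population == "all") {
    thr <- unname(stats::quantile(sim, q, type = qtype))
    excluded <- sim < thr
  } else {
    skipped <- character()
    for (lid in unique(set$meta$leaf_id)) {
      rows <- which(set$meta$leaf_id == lid)
      if (length(rows) < 4L) { skipped <- c(skipped, lid); next }
      thr <- unname(stats::quantile(sim[rows], q, type = qtype))
      excluded[rows] <- sim[rows] < thr
    }
    if (length(skipped))
      warning("cleanse: leaf/leaves with < 4 spectra passed through ",
              "uncleansed: ", paste(skipped, collapse = ", "))
  }

  leaf <- factor(set$meta$leaf_id, unique(set$meta$leaf_id))
  per_leaf <- data.frame(
    leaf_id = levels(leaf),
    before = as.integer(table(leaf)),
    excluded = as.integer(tapply(excluded, leaf, sum)),
    row.names = NULL, stringsAsFactors = FALSE)
  per_leaf$after <- per_leaf$before - per_leaf$excluded

  structure(list(kept = subset_spectra(set, !excluded),
                 excluded_ids = set$meta$spectrum_id[excluded],
                 rule = sprintf("similarity < %s %g-quantile (type %d)",
                                population, q, qtype),
                 per_leaf = per_leaf),
            class = "cleansing_result")
}

#' @export
print.cleansing_result <- function(x, ...) {
  cat("<cleansing_result> rule: ", x$rule, "\n  ",
      sum(x$per_leaf$before), " spectra -> ", sum(x$per_leaf$after),
      " kept (", length(x$excluded_ids), " excluded, ",
      round(100 * length(x$excluded_ids) / max(1, sum(x$per_leaf$before)), 1),
      "%)\n", sep = "")
  invisible(x)
}
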