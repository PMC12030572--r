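#' Baseline-correction parameters
#'
#' Parameters of the iterative moving-average baseline estimator used to
#' remove the broad fluorescence background under leaf Raman spectra.
#' Defaults follow the acquisition protocol this package targets: a 31-point
#' window and 5 iterations.
#'
#' @param window Odd integer window length (points) of the centred moving
#'   average; must be >= 3.
#' @param iterations Number of smooth-and-clip passes; must be >= 1.
#' @param edge_mode Padding rule at the spectrum ends; currently
#'   `"reflect"` (mirror padding without repeating the end point), which
#'   avoids the endpoint droop a truncated window causes.
#' @return An object of class `baseline_params`.
#' @export
baseline_params <- function(window = 31L, iterations = 5L,
                            edge_mode = "reflect") {
  window <- as.integer(window)
  iterations <- as.integer(iterations)
  if (is.na(window) || window < 3L || window %% 2L == 0L)
    stop("baseline_params: window must be an odd integer >= 3", call. = FALSE)
  if (is.na(iterations) || iterations < 1L)
    stop("baseline_params: iterations must be >= 1", call. = FALSE)
  edge_mode <- match.arg(edge_mode, "reflect")
  structure(list(window = window, iterations = iterations,
                 edge_mode = edge_mode),
            class = "baseline_params")
}

# Centred moving average of each column of `mat` with reflect padding.
moving_average_cols <- function(mat, window) {
  n <- nrow(mat)
  h <- (window - 1L) %/% 2L
  if (n <= h)
    stop("moving average: window too large for vector length", call. = FALSE)
  top <- mat[(h + 1L):2L, , drop = FALSE]
  bot <- mat[(n - 1L):(n - h), , drop = FALSE]
  padded <- rbind(top, mat, bot)
  sm <- stats::filter(padded, rep(1 / window, window), sides = 2)
  matrix(sm[(h + 1L):(h + n), ], nrow = n)
}

# Shared smooth-and-clip loop over a channels x spectra matrix.
baseline_cols <- function(mat, params) {
  if (nrow(mat) < params$window)
    stop("fit_baseline: spectrum shorter than the window (",
         params$window, " points)", call. = FALSE)
  est <- mat
  for (k in seq_len(params$iterations)) {
    sm <- moving_average_cols(est, params$window)
    est <- pmin(est, sm)
  }
  est
}

#' Estimate the fluorescence baseline of one spectrum
#'
#' Iterative moving-average baseline estimator: starting from the raw
#' spectrum, each pass replaces the running estimate by the pointwise minimum
#' of itself and its centred moving average. Peaks, being narrow, are averaged
#' down and clipped away, while the broad fluorescence background is
#' preserved, so the final estimate hugs the valleys under the peaks.
#'
#' @param intensity Numeric vector, length >= `params$window`.
#' @param params A [baseline_params()] object.
#' @return Numeric baseline vector of the same length, finite, nowhere above
#'   the running estimate at any clip step.
#' @export
fit_baseline <- function(intensity, params = baseline_params()) {
  stopifnot(inherits(params, "baseline_params"))
  intensity <- as.numeric(intensity)
  if (any(!is.finite(intensity)))
    stop("fit_baseline: intensities must be finite", call. = FALSE)
  as.vector(baseline_cols(matrix(intensity, ncol = 1L), params))
}

#' Baseline-correct every spectrum in a set
#'
#' Subtracts the [fit_baseline()] estimate from each spectrum and clips the
#' result at zero, so all corrected curves sit on or above the
#' zero-intensity axis. Metadata are unchanged.
#'
#' @param set A [spectrum_set()].
#' @param params A [baseline_params()] object.
#' @return A corrected `spectrum_set` with non-negative intensities.
#' @export
baseline_correct <- function(set, params = baseline_params()) {
  stopifnot(inherits(set, "spectrum_set"))
  mat <- t(set$intensities)                    # channels x spectra
  base <- baseline_cols(mat, params)
  corrected <- t(pmax(mat - base, 0))
  spectrum_set(set$wavenumbers, corrected, set$meta)
}

#' Average replicate acquisitions per grid position
#'
#' Instrument protocols acquire several consecutive spectra per template hole
#' and use their mean as the representative spectrum. If the metadata carry a
#' `replicate_id` column, rows sharing (`leaf_id`, `grid_row`, `grid_col`)
#' are averaged channel-wise (unequal replicate counts are allowed — the mean
#' is over the replicates present); without `replicate_id` the set is treated
#' as already averaged and returned unchanged.
#'
#' @param set A [spectrum_set()].
#' @return A `spectrum_set` with one spectrum per grid position.
#' @export
average_replicates <- function(set) {
  stopifnot(inherits(set, "spectrum_set"))
  if (!"replicate_id" %in% names(set$meta)) return(set)

  key <- paste(set$meta$leaf_id, set$meta$grid_row, set$meta$grid_col,
               sep = "\r")
  groups <- split(seq_len(n_spectra(set)), factor(key, unique(key)))
  mat <- matrix(0, nrow = length(groups), ncol = length(set$wavenumbers))
  meta_rows <- integer(length(groups))
  for (i in seq_along(groups)) {
    rows <- groups[[i]]
    mat[i, ] <- colMeans(set$intensities[rows, , drop = FALSE])
    meta_rows[i] <- rows[1]
  }
  meta <- set$meta[meta_rows, setdiff(names(set$meta), "replicate_id"),
                   drop = FALSE]
  meta$spectrum_id <- paste(meta$leaf_id, meta$grid_row, meta$grid_col,
                            sep = "_")
  spectrum_set(set$wavenumbers, mat, meta)
}

#' Normalize spectra to a uniform scale
#'
#' `minmax` (default) maps each spectrum to `(x - min) / (max - min)`, range
#' exactly \[0, 1\]; `vector_norm` divides each spectrum by its Euclidean
#' norm. Cosine similarity is invariant under `vector_norm` by construction.
#' A constant spectrum cannot be min-max scaled: it is set to all zeros with
#' a warning rather than an error.
#'
#' @param set A [spectrum_set()].
#' @param method `"minmax"` or `"vector_norm"`.
#' @return A normalized `spectrum_set`.
#' @export
normalize_spectra <- function(set, method = c("minmax", "vector_norm")) {
  method <- match.arg(method)
  stopifnot(inherits(set, "spectrum_set"))
  mat <- set$intensities
  if (method == "minmax") {
    lo <- apply(mat, 1L, min)
    hi <- apply(mat, 1L, max)
    flat <- hi == lo
    if (any(flat)) {
      warning("normalize_spectra: ", sum(flat),
              " constant spectrum(s) set to zero under minmax")
      hi[flat] <- lo[flat] + 1          # arbitrary; numerator is zero anyway
    }
    mat <- (mat - lo) / (hi - lo)
  } else {
    nrm <- sqrt(rowSums(mat^2))
    if (any(nrm == 0))
      stop("normalize_spectra: zero-norm spectrum under vector_norm",
           call. = FALSE)
    mat <- mat / nrm
  }
  spectrum_set(set$wavenumbers, mat, set$meta)
}

#' Standard preprocessing chain
#'
#' Replicate averaging, baseline correction and normalization in the order
#' the downstream similarity and classification steps expect.
#'
#' @param set A raw [spectrum_set()].
#' @param params A [baseline_params()] object.
#' @param method Normalization method, see [normalize_spectra()].
#' @param range Optional numeric length-2 wavenumber window (cm^-1) to trim
#'   the axis to before correction, e.g. `c(700, 3400)` to drop the
#'   incompletely corrected low-wavenumber region. Default keeps all.
#' @return A preprocessed `spectrum_set`.
#' @export
preprocess_spectra <- function(set, params = baseline_params(),
                               method = "minmax", range = NULL) {
  set <- average_replicates(set)
  if (!is.null(range)) {
    stopifnot(length(range) == 2L, range[1] < range[2])
    keep <- set$wavenumbers >= range[1] & set$wavenumbers <= range[2]
    if (!any(keep)) stop("range trims away the whole axis", call. = FALSE)
    set <- spectrum_set(set$wavenumbers[keep],
                        set$intensities[, keep, drop = FALSE], set$meta)
  }
  set <- baseline_correct(set, params)
  normalize_spectra(set, method)
}
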