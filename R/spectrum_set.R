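#' @keywords internal
"_PACKAGE"

GROUP_LEVELS <- c("CK", "ND", "PD", "KD")
DURATION_LEVELS <- c(24L, 72L, 120L, 168L)
REGION_LEVELS <- c("margin", "vein", "base", "interior")

META_REQUIRED <- c("spectrum_id", "leaf_id", "group", "duration_h",
                   "grid_row", "grid_col")

#' Construct a spectrum set
#'
#' A `spectrum_set` is the central container of the package: a common
#' strictly-increasing wavenumber axis (cm^-1), a matrix of intensity vectors
#' (one row per spectrum, arbitrary counts units), and a metadata table with
#' one record per row of the matrix.
#'
#' @param wavenumbers Numeric vector of spectral positions in cm^-1,
#'   strictly increasing.
#' @param intensities Numeric matrix, one row per spectrum; `ncol` must equal
#'   `length(wavenumbers)`; all values finite.
#' @param meta Data frame with columns `spectrum_id`, `leaf_id`, `group`
#'   (one of CK, ND, PD, KD), `duration_h` (24, 72, 120 or 168), `grid_row`,
#'   `grid_col`, and optionally `replicate_id`. Without `replicate_id` the
#'   combination (`leaf_id`, `grid_row`, `grid_col`) must be unique, i.e. the
#'   set is treated as already replicate-averaged.
#'
#' @return An object of class `spectrum_set`.
#' @export
spectrum_set <- function(wavenumbers, intensities, meta) {
  wavenumbers <- as.numeric(wavenumbers)
  if (!is.matrix(intensities)) intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)

  if (length(wavenumbers) < 1L)
    stop("spectrum_set: empty wavenumber axis", call. = FALSE)
  if (any(!is.finite(wavenumbers)) || any(diff(wavenumbers) <= 0))
    stop("spectrum_set: wavenumbers must be finite and strictly increasing",
         call. = FALSE)
  if (ncol(intensities) != length(wavenumbers))
    stop("spectrum_set: intensity rows must match the wavenumber axis length",
         call. = FALSE)
  if (any(!is.finite(intensities)))
    stop("spectrum_set: intensities must be finite (no NA/NaN/Inf)",
         call. = FALSE)

  missing_cols <- setdiff(META_REQUIRED, names(meta))
  if (length(missing_cols))
    stop("spectrum_set: metadata misses required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(meta) != nrow(intensities))
    stop("spectrum_set: metadata row count (", nrow(meta),
         ") differs from spectrum count (", nrow(intensities), ")",
         call. = FALSE)

  meta$spectrum_id <- as.character(meta$spectrum_id)
  meta$leaf_id <- as.character(meta$leaf_id)
  meta$group <- as.character(meta$group)
  if (!all(meta$group %in% GROUP_LEVELS))
    stop("spectrum_set: group must be one of ",
         paste(GROUP_LEVELS, collapse = ", "), call. = FALSE)
  meta$duration_h <- as.integer(meta$duration_h)
  if (!all(meta$duration_h %in% DURATION_LEVELS))
    stop("spectrum_set: duration_h must be one of ",
         paste(DURATION_LEVELS, collapse = ", "), call. = FALSE)
  meta$grid_row <- as.integer(meta$grid_row)
  meta$grid_col <- as.integer(meta$grid_col)
  if (anyDuplicated(meta$spectrum_id))
    stop("spectrum_set: spectrum_id values must be unique", call. = FALSE)

  key <- paste(meta$leaf_id, meta$grid_row, meta$grid_col)
  if (!"replicate_id" %in% names(meta) && anyDuplicated(key))
    stop("spectrum_set: duplicated (leaf_id, grid_row, grid_col) without a ",
         "replicate_id column", call. = FALSE)

  rownames(intensities) <- meta$spectrum_id
  rownames(meta) <- NULL
  structure(list(wavenumbers = wavenumbers,
                 intensities = intensities,
                 meta = meta),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat("<spectrum_set> ", nrow(x$intensities), " spectra x ",
      length(x$wavenumbers), " channels (",
      min(x$wavenumbers), "-", max(x$wavenumbers), " cm^-1)\n", sep = "")
  cat("  leaves: ", length(unique(x$meta$leaf_id)),
      " | groups: ", paste(sort(unique(x$meta$group)), collapse = "/"),
      " | durations (h): ",
      paste(sort(unique(x$meta$duration_h)), collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Number of spectra in a set
#' @param set A `spectrum_set`.
#' @return Integer count of spectra (matrix rows).
#' @export
n_spectra <- function(set) {
  stopifnot(inherits(set, "spectrum_set"))
  nrow(set$intensities)
}

#' Subset a spectrum set by row
#'
#' @param set A `spectrum_set`.
#' @param idx Integer or logical index over spectra (rows).
#' @return A `spectrum_set` with the selected spectra, metadata aligned.
#' @export
subset_spectra <- function(set, idx) {
  stopifnot(inherits(set, "spectrum_set"))
  spectrum_set(set$wavenumbers,
               set$intensities[idx, , drop = FALSE],
               set$meta[idx, , drop = FALSE])
}

#' Construct a leaf grid
#'
#' Describes the dot-matrix geometry of one leaf: grid pitch, the lattice
#' cells that fall on the leaf, and the anatomical region label of each cell.
#' Row 0 is at the leaf base; column 0 is adjacent to the main vein; physical
#' position is index times `spacing_cm`.
#'
#' @param leaf_id Leaf identifier.
#' @param points Data frame with columns `grid_row`, `grid_col`, `region`
#'   (one of margin, vein, base, interior); one row per in-leaf cell.
#' @param spacing_cm Grid pitch in cm (instrument template default 1.0).
#' @return An object of class `leaf_grid`.
#' @export
leaf_grid <- function(leaf_id, points, spacing_cm = 1.0) {
  points <- as.data.frame(points, stringsAsFactors = FALSE)
  need <- c("grid_row", "grid_col", "region")
  if (!all(need %in% names(points)))
    stop("leaf_grid: points needs columns grid_row, grid_col, region",
         call. = FALSE)
  points$grid_row <- as.integer(points$grid_row)
  points$grid_col <- as.integer(points$grid_col)
  points$region <- as.character(points$region)
  if (!all(points$region %in% REGION_LEVELS))
    stop("leaf_grid: region must be one of ",
         paste(REGION_LEVELS, collapse = ", "), call. = FALSE)
  if (anyDuplicated(paste(points$grid_row, points$grid_col)))
    stop("leaf_grid: duplicated grid cells", call. = FALSE)
  if (any(points$grid_row < 0L) || any(points$grid_col < 0L))
    stop("leaf_grid: grid indices must be non-negative", call. = FALSE)
  if (!is.numeric(spacing_cm) || spacing_cm <= 0)
    stop("leaf_grid: spacing_cm must be positive", call. = FALSE)
  rownames(points) <- NULL
  structure(list(leaf_id = as.character(leaf_id),
                 spacing_cm = as.numeric(spacing_cm),
                 points = points),
            class = "leaf_grid")
}

#' @export
print.leaf_grid <- function(x, ...) {
  cat("<leaf_grid> ", x$leaf_id, ": ", nrow(x$points),
      " cells at ", x$spacing_cm, " cm pitch (",
      paste(sprintf("%s=%d", REGION_LEVELS,
                    vapply(REGION_LEVELS,
                           function(r) sum(x$points$region == r), 1L)),
            collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Label leaf-grid cells with anatomical regions
#'
#' Deterministic proxy for the visually-assigned leaf regions: a cell is
#' `margin` if at least one of its 4-neighbours is off the leaf (the vein-side
#' edge `grid_col - 1 < 0` and the petiole-side edge `grid_row - 1 < 0` do not
#' count, since the blade continues across the vein and ends anatomically at
#' the base, not at a margin), else `vein` if it lies in the two columns
#' adjacent to the main vein (`grid_col <= 1`), else `base` if it lies in the
#' two rows nearest the petiole (`grid_row <= 1`), else `interior`.
#' Precedence margin > vein > base.
#'
#' @param cells Data frame with columns `grid_row`, `grid_col` listing the
#'   in-leaf cells.
#' @return The same data frame with a `region` column appended.
#' @export
assign_regions <- function(cells) {
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  key <- paste(cells$grid_row, cells$grid_col)
  inside <- function(r, c) paste(r, c) %in% key
  region <- character(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    r <- cells$grid_row[i]; c <- cells$grid_col[i]
    nb_r <- c(r + 1L, r); nb_c <- c(c, c + 1L)
    if (r > 0L) { nb_r <- c(nb_r, r - 1L); nb_c <- c(nb_c, c) }
    if (c > 0L) { nb_r <- c(nb_r, r); nb_c <- c(nb_c, c - 1L) }
    nb <- inside(nb_r, nb_c)
    if (!all(nb)) region[i] <- "margin"
    else if (c <= 1L) region[i] <- "vein"
    else if (r <= 1L) region[i] <- "base"
    else region[i] <- "interior"
  }
  cells$region <- region
  cells
}
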