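#' Read a spectral dataset from disk
#'
#' Two plain-text dialects are supported. `wide`: a CSV whose first column is
#' `wavenumber` and whose remaining columns are one spectrum each (header =
#' spectrum id); the instrument-export convention. `long`: a tidy CSV with
#' columns `spectrum_id`, `wavenumber`, `intensity`. Per-spectrum metadata
#' lives in a sidecar CSV with columns `spectrum_id`, `leaf_id`, `group`,
#' `duration_h`, `grid_row`, `grid_col` and optionally `replicate_id`.
#'
#' The wavenumber axis must be identical (strictly increasing) for every
#' spectrum; no interpolation is performed — a mismatch is an error.
#'
#' @param path Path to the spectra CSV.
#' @param meta_path Path to the metadata sidecar CSV.
#' @param dialect `"wide"` or `"long"`.
#' @return A validated [spectrum_set()].
#' @export
read_spectra_table <- function(path, meta_path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("spectra file not found: ", path, call. = FALSE)
  if (!file.exists(meta_path))
    stop("metadata file not found: ", meta_path, call. = FALSE)
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)

  if (dialect == "wide") {
    tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (names(tab)[1] != "wavenumber")
      stop("wide dialect: first column must be 'wavenumber'", call. = FALSE)
    wn <- as.numeric(tab[[1]])
    mat <- t(as.matrix(tab[, -1, drop = FALSE]))
    ids <- names(tab)[-1]
  } else {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("spectrum_id", "wavenumber", "intensity")
    if (!all(need %in% names(tab)))
      stop("long dialect: need columns ", paste(need, collapse = ", "),
           call. = FALSE)
    ids <- unique(tab$spectrum_id)
    pieces <- split(tab, factor(tab$spectrum_id, levels = ids))
    wn <- pieces[[1]]$wavenumber
    mat <- matrix(NA_real_, nrow = length(ids), ncol = length(wn))
    for (i in seq_along(pieces)) {
      p <- pieces[[i]]
      ord <- order(p$wavenumber)
      if (!isTRUE(all.equal(p$wavenumber[ord], wn)))
        stop("long dialect: wavenumber axis differs between spectra ('",
             ids[1], "' vs '", ids[i], "')", call. = FALSE)
      mat[i, ] <- p$intensity[ord]
    }
  }

  if (any(is.na(mat)))
    stop("spectra table contains missing intensities", call. = FALSE)
  ord <- order(wn)
  wn <- wn[ord]
  mat <- mat[, ord, drop = FALSE]

  keep <- match(ids, meta$spectrum_id)
  if (any(is.na(keep)))
    stop("metadata missing for spectra: ",
         paste(utils::head(ids[is.na(keep)], 5), collapse = ", "),
         call. = FALSE)
  spectrum_set(wn, mat, meta[keep, , drop = FALSE])
}

#' Write a spectral dataset to disk
#'
#' Inverse of [read_spectra_table()]: writes the intensity table in the chosen
#' dialect plus the metadata sidecar. Round-trips to within text-float
#' precision (values are printed with 15 significant digits).
#'
#' @param set A non-empty [spectrum_set()].
#' @inheritParams read_spectra_table
#' @return Invisibly, `path`.
#' @export
write_spectra_table <- function(set, path, meta_path,
                                dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(set, "spectrum_set"))
  if (n_spectra(set) == 0L)
    stop("refusing to write an empty spectrum_set", call. = FALSE)

  fmt <- function(x) formatC(x, digits = 15, format = "g")
  if (dialect == "wide") {
    out <- data.frame(wavenumber = fmt(set$wavenumbers),
                      check.names = FALSE, stringsAsFactors = FALSE)
    for (i in seq_len(n_spectra(set)))
      out[[set$meta$spectrum_id[i]]] <- fmt(set$intensities[i, ])
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    n <- n_spectra(set); p <- length(set$wavenumbers)
    out <- data.frame(
      spectrum_id = rep(set$meta$spectrum_id, each = p),
      wavenumber = fmt(rep(set$wavenumbers, times = n)),
      intensity = fmt(as.vector(t(set$intensities))),
      stringsAsFactors = FALSE)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  }
  utils::write.csv(set$meta, meta_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write leaf-grid geometry
#'
#' Leaf grids are stored as a JSON array of objects
#' `{leaf_id, spacing_cm, points: [{grid_row, grid_col, region}, ...]}`.
#'
#' @param path JSON file path.
#' @return `read_leaf_grids`: a named list of [leaf_grid()] objects.
#' @export
read_leaf_grids <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = TRUE)
  if (is.data.frame(raw)) raw <- split(raw, seq_len(nrow(raw)))
  grids <- lapply(raw, function(g) {
    pts <- as.data.frame(g$points)
    leaf_grid(g$leaf_id[[1]], pts, spacing_cm = g$spacing_cm[[1]])
  })
  names(grids) <- vapply(grids, function(g) g$leaf_id, "")
  grids
}

#' @rdname read_leaf_grids
#' @param grids A list of [leaf_grid()] objects.
#' @export
write_leaf_grids <- function(grids, path) {
  if (inherits(grids, "leaf_grid")) grids <- list(grids)
  payload <- lapply(grids, function(g)
    list(leaf_id = g$leaf_id, spacing_cm = g$spacing_cm, points = g$points))
  jsonlite::write_json(unname(payload), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Validate a dataset against its leaf grids
#'
#' Report-only consistency check: per-leaf spectrum counts, orphan positions
#' (a spectrum whose grid cell is absent from its leaf's grid, or a grid cell
#' never sampled), and the group-by-duration tabulation of spectra.
#'
#' @param set A [spectrum_set()].
#' @param grids Named list of [leaf_grid()] objects (names = leaf ids).
#' @return A `validation_report`: list with `per_leaf`, `orphan_spectra`,
#'   `unsampled_cells`, `tabulation` (group x duration counts with margin
#'   totals) and `n_spectra`.
#' @export
validate_dataset <- function(set, grids) {
  stopifnot(inherits(set, "spectrum_set"))
  meta <- set$meta
  per_leaf <- as.data.frame(table(leaf_id = meta$leaf_id),
                            stringsAsFactors = FALSE)
  names(per_leaf)[2] <- "n_spectra"

  orphan <- logical(nrow(meta))
  unsampled <- list()
  for (lid in unique(meta$leaf_id)) {
    rows <- which(meta$leaf_id == lid)
    g <- grids[[lid]]
    if (is.null(g)) { orphan[rows] <- TRUE; next }
    gkey <- paste(g$points$grid_row, g$points$grid_col)
    skey <- paste(meta$grid_row[rows], meta$grid_col[rows])
    orphan[rows] <- !(skey %in% gkey)
    miss <- !(gkey %in% skey)
    if (any(miss))
      unsampled[[lid]] <- cbind(leaf_id = lid,
                                g$points[miss, c("grid_row", "grid_col")])
  }
  unsampled <- if (length(unsampled)) do.call(rbind, unsampled) else
    data.frame(leaf_id = character(), grid_row = integer(),
               grid_col = integer())

  tab <- table(group = factor(meta$group, GROUP_LEVELS),
               duration_h = factor(meta$duration_h, DURATION_LEVELS))
  structure(list(per_leaf = per_leaf,
                 orphan_spectra = meta[orphan, , drop = FALSE],
                 unsampled_cells = unsampled,
                 tabulation = add_margin_totals(unclass(tab)),
                 n_spectra = n_spectra(set)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> ", x$n_spectra, " spectra, ",
      nrow(x$per_leaf), " leaves; ", nrow(x$orphan_spectra),
      " orphan spectra, ", nrow(x$unsampled_cells),
      " unsampled grid cells\n", sep = "")
  print(x$tabulation)
  invisible(x)
}

#' Append margin totals to a count table
#'
#' Adds a `Total` column (row sums) and a `Total` row (column sums) to a
#' numeric count matrix — the tabulation layout used for outlier and
#' below-quartile counts by treatment group and stress duration.
#'
#' @param counts Numeric matrix (e.g. groups x durations).
#' @return The matrix extended by one `Total` row and one `Total` column; the
#'   corner cell is the grand total.
#' @export
add_margin_totals <- function(counts) {
  counts <- as.matrix(counts)
  out <- cbind(counts, Total = rowSums(counts))
  rbind(out, Total = colSums(out))
}
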