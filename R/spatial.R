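#' Project below-quartile similarities onto the leaf grid
#'
#' Builds the masked heat-map matrix for one leaf: cells whose spectrum falls
#' below the lower quartile keep their similarity value, every other in-leaf
#' cell is set to 1.0, and cells outside the leaf are `NA`. This highlights
#' where the low-similarity positions sit on the blade.
#'
#' @param sims A flagged [similarity_table()] (needs `below_q1`).
#' @param grid The [leaf_grid()] of one leaf appearing in `sims`.
#' @return A `similarity_map`: list with `leaf_id`, `values` (matrix over the
#'   grid bounding box, rows = `grid_row` 0.., cols = `grid_col` 0..),
#'   `flagged` (logical matrix, same shape) and `grid`.
#' @export
build_similarity_map <- function(sims, grid) {
  stopifnot(inherits(sims, "similarity_table"), inherits(grid, "leaf_grid"))
  rows <- which(sims$leaf_id == grid$leaf_id)
  if (!length(rows))
    stop("build_similarity_map: no spectra for leaf '", grid$leaf_id, "'",
         call. = FALSE)
  sub <- sims[rows, , drop = FALSE]
  if (any(is.na(sub$below_q1)))
    stop("build_similarity_map: below_q1 not set; run boxplot_outliers()",
         call. = FALSE)
  gkey <- paste(grid$points$grid_row, grid$points$grid_col)
  skey <- paste(sub$grid_row, sub$grid_col)
  if (any(!skey %in% gkey))
    stop("build_similarity_map: spectra at positions absent from the grid: ",
         paste(utils::head(skey[!skey %in% gkey], 5), collapse = "; "),
         call. = FALSE)

  nr <- max(grid$points$grid_row) + 1L
  nc <- max(grid$points$grid_col) + 1L
  values <- matrix(NA_real_, nr, nc,
                   dimnames = list(seq_len(nr) - 1L, seq_len(nc) - 1L))
  flagged <- matrix(FALSE, nr, nc)
  values[cbind(grid$points$grid_row + 1L, grid$points$grid_col + 1L)] <- 1.0
  low <- which(sub$below_q1)
  values[cbind(sub$grid_row[low] + 1L, sub$grid_col[low] + 1L)] <-
    sub$similarity[low]
  flagged[cbind(sub$grid_row[low] + 1L, sub$grid_col[low] + 1L)] <- TRUE
  structure(list(leaf_id = grid$leaf_id, values = values, flagged = flagged,
                 grid = grid),
            class = "similarity_map")
}

#' @export
print.similarity_map <- function(x, ...) {
  cat("<similarity_map> ", x$leaf_id, ": ", sum(!is.na(x$values)),
      " in-leaf cells, ", sum(x$flagged), " below-quartile\n", sep = "")
  invisible(x)
}

#' Region enrichment of flagged positions
#'
#' Quantifies where the low-similarity positions concentrate: for each
#' anatomical region, the count and fraction of flagged positions, the
#' baseline fraction of all positions the region occupies, and their ratio.
#' A ratio above 1 means the region holds more flagged positions than its
#' share of the leaf area would predict.
#'
#' @param maps A [build_similarity_map()] result or a list of them.
#' @return An `enrichment_report` data frame with columns `region`,
#'   `n_cells`, `n_flagged`, `frac_cells`, `frac_flagged`, `enrichment`
#'   (ratio `frac_flagged / frac_cells`; `NA` when no position is flagged).
#' @export
region_enrichment <- function(maps) {
  if (inherits(maps, "similarity_map")) maps <- list(maps)
  cells <- integer(length(REGION_LEVELS))
  flags <- integer(length(REGION_LEVELS))
  names(cells) <- names(flags) <- REGION_LEVELS
  for (m in maps) {
    stopifnot(inherits(m, "similarity_map"))
    pts <- m$grid$points
    fl <- m$flagged[cbind(pts$grid_row + 1L, pts$grid_col + 1L)]
    for (r in REGION_LEVELS) {
      cells[r] <- cells[r] + sum(pts$region == r)
      flags[r] <- flags[r] + sum(fl & pts$region == r)
    }
  }
  total_cells <- sum(cells)
  total_flags <- sum(flags)
  frac_cells <- cells / total_cells
  frac_flagged <- if (total_flags > 0) flags / total_flags else
    rep(NA_real_, length(flags))
  out <- data.frame(region = REGION_LEVELS,
                    n_cells = as.integer(cells),
                    n_flagged = as.integer(flags),
                    frac_cells = frac_cells,
                    frac_flagged = frac_flagged,
                    enrichment = frac_flagged / frac_cells,
                    row.names = NULL)
  class(out) <- c("enrichment_report", "data.frame")
  out
}

#' Export a similarity map
#'
#' `csv_matrix` writes the masked value matrix as CSV with empty fields for
#' out-of-leaf cells (round-trips through [read_similarity_map_csv()]).
#' `png_heatmap` renders a monotone grey heat map in which darker cells are
#' closer to 1.0, so the pale cells are the low-similarity positions.
#'
#' @param map A `similarity_map`.
#' @param path Output file path.
#' @param format `"csv_matrix"` or `"png_heatmap"`.
#' @return Invisibly, `path`.
#' @export
export_map <- function(map, path, format = c("csv_matrix", "png_heatmap")) {
  format <- match.arg(format)
  stopifnot(inherits(map, "similarity_map"))
  if (format == "csv_matrix") {
    utils::write.table(map$values, path, sep = ",", na = "",
                       row.names = FALSE, col.names = FALSE)
  } else {
    v <- map$values
    grDevices::png(path, width = 160 * ncol(v), height = 160 * nrow(v))
    op <- graphics::par(mar = c(2, 2, 2, 1))
    on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
    # flip rows so the leaf base (row 0) is at the bottom of the plot
    z <- t(v[nrow(v):1, , drop = FALSE])
    graphics::image(z = z, col = grDevices::gray(seq(1, 0, length.out = 256)),
                    zlim = c(min(v, na.rm = TRUE), 1), axes = FALSE,
                    main = map$leaf_id)
  }
  invisible(path)
}

#' Re-read a similarity map value matrix written by [export_map()]
#'
#' @param path CSV path written with `format = "csv_matrix"`.
#' @return Numeric matrix with `NA` for out-of-leaf cells.
#' @export
read_similarity_map_csv <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", header = FALSE,
                              na.strings = "", colClasses = "numeric"))
}
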