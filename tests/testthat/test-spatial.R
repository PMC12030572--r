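# Build a similarity_table directly from values laid over a grid.
sim_tab_for_grid <- function(grid, values, leaf_id = grid$leaf_id) {
  pts <- grid$points
  n <- nrow(pts)
  meta <- data.frame(spectrum_id = paste0(leaf_id, "_", seq_len(n)),
                     leaf_id = leaf_id, group = "CK", duration_h = 24L,
                     grid_row = pts$grid_row, grid_col = pts$grid_col)
  structure(cbind(meta, similarity = values, is_outlier = NA, below_q1 = NA),
            class = c("similarity_table", "data.frame"))
}

demo_grid <- function(leaf_id = "L") {
  cells <- assign_regions(expand.grid(grid_row = 0:3, grid_col = 0:3))
  leaf_grid(leaf_id, cells)
}

test_that("the masked map keeps below-quartile cells and 1.0 elsewhere", {
  g <- demo_grid()
  tab <- boxplot_outliers(sim_tab_for_grid(g, seq(0.9, 0.99, length.out = 16)),
                          "all")
  m <- build_similarity_map(tab, g)
  expect_equal(sum(m$flagged), sum(tab$below_q1))
  expect_equal(sum(m$values < 1, na.rm = TRUE), sum(tab$below_q1))
  in_leaf_unflagged <- !is.na(m$values) & !m$flagged
  expect_true(all(m$values[in_leaf_unflagged] == 1.0))

  # no below-quartile rows -> all in-leaf cells 1.0
  tab2 <- sim_tab_for_grid(g, rep(0.99, 16))
  tab2$below_q1 <- FALSE; tab2$is_outlier <- FALSE
  m2 <- build_similarity_map(tab2, g)
  expect_true(all(m2$values[!is.na(m2$values)] == 1.0))

  # out-of-leaf cells are NA, never 1.0
  gpart <- leaf_grid("L", assign_regions(
    data.frame(grid_row = c(0L, 0L, 1L, 1L), grid_col = c(0L, 1L, 0L, 1L))))
  tab3 <- boxplot_outliers(sim_tab_for_grid(gpart, c(0.9, 0.95, 0.97, 0.99)),
                           "all")
  # put one spectrum outside the grid -> orphan error
  bad <- tab3; bad$grid_row[1] <- 7L
  expect_error(build_similarity_map(bad, gpart), "absent from the grid")
})

test_that("map conservation holds across leaves", {
  set.seed(71)
  syn <- generate_dataset(small_cfg(seed = 71))
  pre <- preprocess_spectra(syn$set)
  flagged <- boxplot_outliers(similarity_table(pre), "per_leaf")
  maps <- lapply(syn$grids, function(g) build_similarity_map(flagged, g))
  expect_equal(sum(vapply(maps, function(m) sum(m$flagged), 1L)),
               sum(flagged$below_q1))
})

test_that("region enrichment follows the flag placement", {
  g <- demo_grid()
  pts <- g$points
  # all flags on margin cells -> margin ratio = 1 / margin area fraction
  vals <- rep(0.99, nrow(pts))
  tab <- sim_tab_for_grid(g, vals)
  tab$below_q1 <- pts$region == "margin"
  tab$is_outlier <- FALSE
  m <- build_similarity_map(tab, g)
  e <- region_enrichment(m)
  frac_margin <- mean(pts$region == "margin")
  expect_equal(e$enrichment[e$region == "margin"], 1 / frac_margin)
  expect_equal(e$n_flagged[e$region == "interior"], 0L)

  # no flags at all -> ratios reported missing
  tab$below_q1 <- FALSE
  e0 <- region_enrichment(build_similarity_map(tab, g))
  expect_true(all(is.na(e0$enrichment)))

  # enrichment is invariant to leaf relabeling
  tabA <- tab; tabA$below_q1 <- pts$region == "vein"
  mA <- build_similarity_map(tabA, g)
  gB <- demo_grid("Z")
  tabB <- sim_tab_for_grid(gB, vals)
  tabB$below_q1 <- pts$region == "vein"; tabB$is_outlier <- FALSE
  mB <- build_similarity_map(tabB, gB)
  expect_equal(region_enrichment(mA)$enrichment,
               region_enrichment(mB)$enrichment)
})

test_that("uniformly random flags give enrichment near 1", {
  g <- demo_grid()
  pts <- g$points
  set.seed(81)
  agg_flags <- stats::setNames(numeric(4), c("margin", "vein", "base",
                                             "interior"))
  total <- 0
  for (i in 1:20) {
    flags <- sample(nrow(pts), 4)
    tab <- sim_tab_for_grid(g, rep(0.99, nrow(pts)))
    tab$below_q1 <- seq_len(nrow(pts)) %in% flags
    tab$is_outlier <- FALSE
    e <- region_enrichment(build_similarity_map(tab, g))
    agg_flags <- agg_flags + e$n_flagged[match(names(agg_flags), e$region)]
    total <- total + 4
  }
  frac <- agg_flags / total
  avail <- vapply(names(agg_flags), function(r) mean(pts$region == r), 1)
  # binomial noise over 80 draws: all aggregated ratios within wide CI of 1
  ratio <- frac / avail
  expect_true(all(ratio > 0.5 & ratio < 1.8))
})

test_that("map export round-trips through CSV and renders PNG", {
  g <- demo_grid()
  tab <- boxplot_outliers(sim_tab_for_grid(g, seq(0.9, 0.99,
                                                  length.out = 16)), "all")
  m <- build_similarity_map(tab, g)
  f <- tempfile(fileext = ".csv")
  export_map(m, f, "csv_matrix")
  back <- read_similarity_map_csv(f)
  expect_equal(unname(back), unname(m$values))

  # missing cells -> empty CSV fields
  gpart <- leaf_grid("L", assign_regions(
    data.frame(grid_row = c(0L, 0L, 1L), grid_col = c(0L, 1L, 0L))))
  tpart <- sim_tab_for_grid(gpart, c(0.9, 0.95, 0.99))
  tpart$below_q1 <- c(TRUE, FALSE, FALSE)
  tpart$is_outlier <- FALSE
  mpart <- build_similarity_map(tpart, gpart)
  f2 <- tempfile(fileext = ".csv")
  export_map(mpart, f2, "csv_matrix")
  expect_true(any(grepl(",$|^,", readLines(f2))))
  expect_equal(unname(read_similarity_map_csv(f2)), unname(mpart$values))

  # 1x1 map
  g1 <- leaf_grid("solo", data.frame(grid_row = 0L, grid_col = 0L,
                                     region = "margin"))
  t1 <- sim_tab_for_grid(g1, 0.95)
  t1$below_q1 <- TRUE; t1$is_outlier <- FALSE
  m1 <- build_similarity_map(t1, g1)
  f3 <- tempfile(fileext = ".csv")
  export_map(m1, f3, "csv_matrix")
  expect_equal(dim(read_similarity_map_csv(f3)), c(1L, 1L))

  fp <- tempfile(fileext = ".png")
  export_map(m, fp, "png_heatmap")
  expect_gt(file.size(fp), 0)
})
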