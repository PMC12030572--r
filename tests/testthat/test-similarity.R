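test_that("cosine similarity matches its analytic anchors", {
  expect_equal(cosine_similarity(c(2, 5, 1), c(2, 5, 1)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 0, 1), c(1, 1, 0)), 0.5)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero-norm")
  expect_error(cosine_similarity(1:3, 1:4), "equal positive length")
})

test_that("cosine similarity is scale-invariant and symmetric", {
  set.seed(21)
  for (i in 1:200) {
    a <- stats::rnorm(17); b <- stats::rnorm(17)
    if (sum(a^2) == 0 || sum(b^2) == 0) next
    cc <- stats::runif(1, 1e-3, 1e3)
    expect_equal(cosine_similarity(cc * a, b), cosine_similarity(a, b),
                 tolerance = 1e-12)
    expect_equal(cosine_similarity(a, b), cosine_similarity(b, a),
                 tolerance = 1e-12)
  }
})

test_that("leaf mean spectrum is the channel-wise average", {
  wn <- c(200, 300)
  meta <- data.frame(spectrum_id = c("a", "b"), leaf_id = "L", group = "CK",
                     duration_h = 24L, grid_row = 0:1, grid_col = 0L)
  s <- spectrum_set(wn, rbind(c(1, 3), c(3, 1)), meta)
  expect_equal(unname(leaf_mean_spectrum(s, "L")), c(2, 2))
  one <- subset_spectra(s, 1)
  expect_equal(unname(leaf_mean_spectrum(one, "L")), c(1, 3))
  expect_equal(cosine_similarity(one$intensities[1, ],
                                 leaf_mean_spectrum(one, "L")), 1)
  expect_error(leaf_mean_spectrum(s, "nope"), "unknown leaf_id")
})

test_that("similarity table scores every spectrum against its leaf mean", {
  # identical spectra within a leaf -> all similarities 1
  wn <- c(200, 300, 400)
  meta <- data.frame(spectrum_id = paste0("s", 1:4), leaf_id = "L",
                     group = "CK", duration_h = 24L,
                     grid_row = c(0L, 0L, 1L, 1L), grid_col = c(0L, 1L, 0L, 1L))
  s <- spectrum_set(wn, matrix(rep(c(1, 2, 3), each = 4), 4), meta)
  tab <- similarity_table(s)
  expect_equal(nrow(tab), 4L)
  expect_true(all(abs(tab$similarity - 1) < 1e-12))

  # a strongly perturbed position is the strict minimum on its leaf
  set.seed(31)
  syn <- generate_dataset(small_cfg(
    seed = 31, anomaly_fractions = c(margin = 0, vein = 0, base = 0,
                                     interior = 0)))
  pre <- preprocess_spectra(syn$set)
  lid <- pre$meta$leaf_id[1]
  rows <- which(pre$meta$leaf_id == lid)
  victim <- rows[5]
  perturbed <- pre$intensities
  chans <- sample(ncol(perturbed), 200)
  perturbed[victim, chans] <- perturbed[victim, chans] * 3 + 0.5
  tab2 <- similarity_table(spectrum_set(pre$wavenumbers, perturbed, pre$meta))
  expect_equal(which.min(tab2$similarity[rows]), 5L)
  expect_equal(nrow(tab2), n_spectra(pre))
})

test_that("box-plot flags agree with a brute-force quantile oracle", {
  # hand-sized case: one clear outlier
  meta <- data.frame(spectrum_id = paste0("s", 1:20), leaf_id = "L",
                     group = "CK", duration_h = 24L,
                     grid_row = rep(0:4, 4), grid_col = rep(0:3, each = 5))
  vals <- c(rep(0.99, 19), 0.5)
  tab <- structure(cbind(meta, similarity = vals, is_outlier = NA,
                         below_q1 = NA),
                   class = c("similarity_table", "data.frame"))
  out <- boxplot_outliers(tab, "all")
  expect_equal(which(out$is_outlier), 20L)
  expect_equal(sum(out$below_q1), 1L)

  # all equal -> no flags
  tab$similarity <- 0.99
  expect_equal(sum(boxplot_outliers(tab, "all")$is_outlier), 0L)

  # random populations vs sort-based oracle
  set.seed(41)
  for (i in 1:50) {
    n <- sample(4:200, 1)
    x <- stats::runif(n)
    m2 <- data.frame(spectrum_id = paste0("r", 1:n), leaf_id = "L",
                     group = "CK", duration_h = 24L,
                     grid_row = seq_len(n), grid_col = 0L)
    t2 <- structure(cbind(m2, similarity = x, is_outlier = NA,
                          below_q1 = NA),
                    class = c("similarity_table", "data.frame"))
    got <- boxplot_outliers(t2, "all")
    q1 <- quantile_oracle(x, 0.25); q3 <- quantile_oracle(x, 0.75)
    expect_identical(got$is_outlier, x < q1 - 1.5 * (q3 - q1))
    expect_identical(got$below_q1, x < q1)
  }

  small <- t2[1:3, ]; class(small) <- class(t2)
  expect_error(boxplot_outliers(small, "all"), "fewer than 4")
})

test_that("flag tabulation conserves the total count", {
  set.seed(51)
  syn <- generate_dataset(small_cfg(seed = 51))
  pre <- preprocess_spectra(syn$set)
  flagged <- boxplot_outliers(similarity_table(pre), "all")
  tab <- tabulate_flags(flagged, "is_outlier")
  expect_equal(tab["Total", "Total"], sum(flagged$is_outlier))
  tab2 <- tabulate_flags(flagged, "below_q1")
  expect_equal(tab2["Total", "Total"], sum(flagged$below_q1))
  unflagged <- similarity_table(pre)
  expect_error(tabulate_flags(unflagged), "flags not set")
})

test_that("repeatability minima are prefix minima against a fixed mean", {
  # identical replicates -> everything 1
  stream <- matrix(rep(c(1, 2, 3, 4), each = 30), nrow = 30)
  rep1 <- repeatability_report(list(P1 = stream))
  expect_true(all(rep1$minima == 1))
  expect_true(rep1$all_above)

  # random streams: minima non-increasing in the collection count
  set.seed(61)
  for (i in 1:20) {
    m <- matrix(stats::runif(30 * 8, 1, 2), nrow = 30)
    r <- repeatability_report(list(P = m))
    expect_true(all(diff(r$minima[1, ]) <= 1e-15))
  }

  # short stream: restricted counts with a warning
  expect_warning(r2 <- repeatability_report(list(P = stream[1:15, ])),
                 "restricting")
  expect_equal(r2$counts, 10L)

  # cross-position means are plain column means
  minima <- rbind(P1 = c(0.95, 0.94), P2 = c(0.97, 0.96))
  colnames(minima) <- c("10", "20")
  s <- repeatability_summary(minima, floor = 0.9)
  expect_equal(unname(s$means), c(0.96, 0.95))
  expect_true(s$all_above)
})
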