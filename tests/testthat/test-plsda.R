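test_that("interleaved split alternates within each stratum", {
  # 10 rows, one stratum -> 5/5
  meta10 <- data.frame(spectrum_id = paste0("s", 1:10), leaf_id = "L",
                       group = "CK", duration_h = 24L,
                       grid_row = 0:9, grid_col = 0L)
  s10 <- spectrum_set(c(200, 300), matrix(1:20, 10), meta10)
  sp <- interleaved_split(s10)
  expect_equal(n_spectra(sp$train), 5L)
  expect_equal(n_spectra(sp$test), 5L)
  expect_equal(sp$train$meta$spectrum_id, paste0("s", c(1, 3, 5, 7, 9)))

  # 11 rows -> 6 train / 5 test
  meta11 <- rbind(meta10, data.frame(spectrum_id = "s11", leaf_id = "L",
                                     group = "CK", duration_h = 24L,
                                     grid_row = 10L, grid_col = 0L))
  s11 <- spectrum_set(c(200, 300), matrix(1, 11, 2), meta11)
  sp11 <- interleaved_split(s11)
  expect_equal(n_spectra(sp11$train), 6L)

  # stratified: every group x duration keeps ceiling(n/2) training rows
  set.seed(121)
  syn <- generate_dataset(small_cfg(seed = 121))
  sp2 <- interleaved_split(syn$set)
  for (g in unique(syn$set$meta$group)) {
    for (d in unique(syn$set$meta$duration_h)) {
      n_all <- sum(syn$set$meta$group == g & syn$set$meta$duration_h == d)
      n_tr <- sum(sp2$train$meta$group == g & sp2$train$meta$duration_h == d)
      expect_equal(n_tr, ceiling(n_all / 2))
    }
  }
})

test_that("PLS-DA separates constructed classes and is deterministic", {
  set.seed(131)
  s <- two_class_set()
  m <- fit_plsda(s, 2)
  pred <- predict(m, s)
  expect_equal(as.character(pred), s$meta$group)   # 100% training accuracy

  cm <- table(s$meta$group, pred)
  expect_equal(sum(cm), n_spectra(s))

  # determinism: the same sample predicts the same label twice
  dup_meta <- s$meta[c(1, 1), ]
  dup_meta$spectrum_id <- c("d1", "d2")
  dup_meta$leaf_id <- c("dA", "dB")
  dup <- spectrum_set(s$wavenumbers, s$intensities[c(1, 1), ], dup_meta)
  p2 <- predict(m, dup)
  expect_equal(p2[1], p2[2])

  single <- subset_spectra(s, s$meta$group == "CK")
  expect_error(fit_plsda(single, 1), "single class")
  expect_error(fit_plsda(s, 0), "n_lv")
  expect_error(fit_plsda(s, 10000), "n_lv")
})

test_that("macro metrics follow their definitions", {
  perfect <- diag(c(5, 5, 5, 5))
  dimnames(perfect) <- list(GROUPS <- c("CK", "ND", "PD", "KD"), GROUPS)
  mm <- macro_metrics(perfect)
  expect_equal(mm$macro_P, 100)
  expect_equal(mm$macro_R, 100)
  expect_equal(mm$macro_F1, 100)

  cm <- matrix(c(5, 0, 5, 10), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  mm2 <- macro_metrics(cm)
  expect_equal(mm2$macro_P, (100 + 200 / 3) / 2, tolerance = 1e-9)
  expect_equal(mm2$macro_R, (50 + 100) / 2)
  expect_equal(mm2$f1, 2 * mm2$precision * mm2$recall /
                 (mm2$precision + mm2$recall))

  # permutation invariance of macro metrics
  set.seed(141)
  c4 <- matrix(rpois(16, 5) + 1, 4, 4)
  p <- sample(4)
  expect_equal(macro_metrics(c4)$macro_F1,
               macro_metrics(c4[p, p])$macro_F1)

  # a never-predicted class earns precision 0, with a warning
  cm0 <- matrix(c(3, 2, 0, 0), 2, 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  expect_warning(mm3 <- macro_metrics(cm0), "never predicted")
  expect_equal(unname(mm3$precision[2]), 0)
})

test_that("evaluation reports confusion, misdiagnoses and percentages", {
  set.seed(151)
  s <- two_class_set(n_per_class = 30L)
  sp <- interleaved_split(s)
  m <- fit_plsda(sp$train, 2)
  rep <- evaluate_model(m, sp$test)
  expect_equal(sum(rep$confusion), rep$n_samples)
  expect_equal(rep$mds, sum(rep$confusion) - sum(diag(rep$confusion)))
  expect_true(rep$macro_F1 >= 0 && rep$macro_F1 <= 100)
  expect_error(evaluate_model(m, subset_spectra(s, integer(0))), "empty")
})

test_that("LV selection picks the smallest stable setting", {
  set.seed(161)
  # one latent direction fully separates two classes
  s <- two_class_set(n_per_class = 25L, shift = 8, sd = 0.3)
  sel <- select_lvs(s, k = 5, lv_max = 8)
  expect_equal(sel$best_lv, 1L)
  expect_lte(sel$best_lv, 8L)
  expect_equal(nrow(sel$cv_report), 8L)
  # chosen CV F1 is within tau of the grid maximum by construction
  expect_gte(sel$best_cv$macro_F1, max(sel$cv_report$macro_F1) - 0.5)

  tiny <- subset_spectra(s, c(1:3, 26:28))
  expect_error(select_lvs(tiny, k = 5), "fewer samples")
})

test_that("1-LV PLS-DA matches a univariate threshold oracle", {
  set.seed(171)
  agree <- numeric(5)
  for (i in 1:5) {
    n <- 40L
    informative <- stats::rnorm(n, rep(c(0, 3), each = n / 2), 1)
    mat <- cbind(informative,
                 matrix(stats::rnorm(n * 19, 5, 0.2), n))
    mat <- mat - min(mat)
    meta <- data.frame(spectrum_id = paste0("u", 1:n),
                       leaf_id = paste0("L", 1:n),
                       group = rep(c("CK", "ND"), each = n / 2),
                       duration_h = 24L, grid_row = 0L, grid_col = 1:n)
    s <- spectrum_set(seq(200, length.out = 20, by = 10), mat, meta)
    sp <- interleaved_split(s)
    m <- fit_plsda(sp$train, 1)
    pls_lab <- as.character(predict(m, sp$test))
    # oracle: threshold on the informative channel at the midpoint of the
    # class means estimated on the training half
    tr <- sp$train
    mid <- mean(tapply(tr$intensities[, 1], tr$meta$group, mean))
    thr_lab <- ifelse(sp$test$intensities[, 1] > mid, "ND", "CK")
    agree[i] <- mean(pls_lab == thr_lab)
  }
  expect_true(all(agree >= 0.95))
})

test_that("comparing a dataset against itself gives zero deltas", {
  set.seed(181)
  syn <- generate_dataset(small_cfg(seed = 181))
  pre <- preprocess_spectra(syn$set)
  sub <- subset_spectra(pre, pre$meta$duration_h == 24L)
  cmp <- before_after_comparison(sub, sub, durations = 24L)
  expect_equal(nrow(cmp$models), 2L)
  expect_true(all(cmp$deltas$d_lv == 0))
  expect_true(all(cmp$deltas$d_mds == 0))
  expect_true(all(cmp$deltas$d_test_f1 == 0))
  expect_equal(cmp$models$n_samples, rep(n_spectra(sub), 2))
})
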