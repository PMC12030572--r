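#' Interleaved train/test split
#'
#' Divides the spectra evenly into training and test halves at an interval
#' of one along the collection sequence (file row order), stratified within
#' each group-by-duration cell so both halves contain every class: within a
#' stratum the 1st, 3rd, 5th, ... spectra go to training and the 2nd, 4th,
#' ... to the test set, so an odd stratum gives the extra spectrum to
#' training.
#'
#' @param set A [spectrum_set()].
#' @return List with elements `train` and `test`, both `spectrum_set`s.
#' @export
interleaved_split <- function(set) {
  stopifnot(inherits(set, "spectrum_set"))
  stratum <- paste(set$meta$group, set$meta$duration_h)
  take_train <- logical(n_spectra(set))
  for (s in unique(stratum)) {
    rows <- which(stratum == s)
    take_train[rows] <- (seq_along(rows) - 1L) %% 2L == 0L
  }
  list(train = subset_spectra(set, take_train),
       test = subset_spectra(set, !take_train))
}

plsda_design_matrix <- function(set) {
  x <- set$intensities
  colnames(x) <- paste0("w", seq_len(ncol(x)))
  x
}

#' Fit a PLS-DA classifier
#'
#' Partial least squares regression of the spectra onto the one-hot encoded
#' class matrix (via [mixOmics::plsda()], unscaled, mean-centred); a sample
#' is assigned to the class with the largest continuous class score. Score
#' ties are broken by class order CK < ND < PD < KD, so predictions are
#' deterministic given the input order.
#'
#' @param train A [spectrum_set()] with at least two classes present.
#' @param n_lv Number of latent variables, between 1 and
#'   `min(n_samples - 1, n_channels)`.
#' @return An object of class `plsda_model`.
#' @export
fit_plsda <- function(train, n_lv) {
  stopifnot(inherits(train, "spectrum_set"))
  y <- factor(train$meta$group, GROUP_LEVELS)
  y <- droplevels(y)
  if (nlevels(y) < 2L)
    stop("fit_plsda: training set holds a single class", call. = FALSE)
  n_lv <- as.integer(n_lv)
  lv_cap <- min(n_spectra(train) - 1L, length(train$wavenumbers))
  if (n_lv < 1L || n_lv > lv_cap)
    stop("fit_plsda: n_lv must be in [1, ", lv_cap, "]", call. = FALSE)
  x <- plsda_design_matrix(train)
  # zero-clipped baseline correction can leave all-zero channels, which make
  # mixOmics warn about zero-variance columns when it reports explained
  # variance; the fit itself is unaffected
  fit <- withCallingHandlers(
    mixOmics::plsda(x, y, ncomp = n_lv, scale = FALSE),
    warning = function(w) {
      if (grepl("standard deviation is zero", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  structure(list(fit = fit, n_lv = n_lv, classes = levels(y)),
            class = "plsda_model")
}

# Class predictions of a plsda_model at every 1..n_lv, argmax with
# first-maximum (class-order) tie-break. Returns a character matrix
# n_samples x n_lv.
predict_all_lv <- function(model, set) {
  x <- plsda_design_matrix(set)
  scores <- stats::predict(model$fit, x)$predict  # n x nclass x ncomp
  cls <- model$classes
  out <- matrix(NA_character_, nrow = dim(scores)[1], ncol = dim(scores)[3])
  for (k in seq_len(dim(scores)[3]))
    out[, k] <- cls[apply(scores[, , k, drop = FALSE], 1L, which.max)]
  out
}

#' @export
#' @param object A `plsda_model`.
#' @param newdata A [spectrum_set()] on the same wavenumber axis.
#' @param ... Unused.
#' @rdname fit_plsda
predict.plsda_model <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "spectrum_set"))
  factor(predict_all_lv(object, newdata)[, object$n_lv], GROUP_LEVELS)
}

#' Macro-averaged classification metrics
#'
#' Per-class precision (column-wise), recall (row-wise) and
#' `F1 = 2PR / (P + R)` from a confusion matrix with true classes in rows
#' and predicted classes in columns, averaged with equal class weights and
#' expressed as percentages. A class never predicted has precision 0 (with a
#' warning), matching the convention that an absent prediction earns no
#' credit; an F1 with `P + R = 0` is 0.
#'
#' @param cm Square numeric confusion matrix, rows = true, cols = predicted.
#' @return List with `macro_P`, `macro_R`, `macro_F1` (percent) and the
#'   per-class vectors `precision`, `recall`, `f1` (fractions).
#' @export
macro_metrics <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm))
  tp <- diag(cm)
  pred_n <- colSums(cm)
  true_n <- rowSums(cm)
  if (any(pred_n == 0))
    warning("macro_metrics: class(es) never predicted; precision set to 0: ",
            paste(colnames(cm)[pred_n == 0], collapse = ", "))
  precision <- ifelse(pred_n > 0, tp / pred_n, 0)
  recall <- ifelse(true_n > 0, tp / true_n, 0)
  pr <- precision + recall
  f1 <- ifelse(pr > 0, 2 * precision * recall / pr, 0)
  list(macro_P = 100 * mean(precision),
       macro_R = 100 * mean(recall),
       macro_F1 = 100 * mean(f1),
       precision = precision, recall = recall, f1 = f1)
}

#' Evaluate a fitted PLS-DA model on a labelled test set
#'
#' @param model A [fit_plsda()] model.
#' @param test A labelled [spectrum_set()].
#' @return A `model_report`: list with `n_samples`, `n_lv`,
#'   `confusion` (true x predicted counts over CK/ND/PD/KD), `mds`
#'   (misdiagnoses = off-diagonal total) and the macro metrics in percent.
#' @export
evaluate_model <- function(model, test) {
  stopifnot(inherits(model, "plsda_model"), inherits(test, "spectrum_set"))
  if (n_spectra(test) == 0L)
    stop("evaluate_model: empty test set", call. = FALSE)
  pred <- predict(model, test)
  truth <- factor(test$meta$group, GROUP_LEVELS)
  cm <- table(truth = truth, predicted = pred)
  cm <- unclass(cm)
  present <- levels(truth)[rowSums(cm) > 0 | colSums(cm) > 0]
  mm <- macro_metrics(cm[present, present, drop = FALSE])
  structure(list(n_samples = n_spectra(test), n_lv = model$n_lv,
                 confusion = cm, mds = sum(cm) - sum(diag(cm)),
                 macro_P = mm$macro_P, macro_R = mm$macro_R,
                 macro_F1 = mm$macro_F1),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat("<model_report> n=", x$n_samples, " LVs=", x$n_lv, " MDs=", x$mds,
      sprintf("  macro-P/R/F1 = %.2f/%.2f/%.2f %%\n",
              x$macro_P, x$macro_R, x$macro_F1), sep = "")
  invisible(x)
}

# Deterministic stratified K folds: round-robin over row order within class.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    rows <- which(y == cl)
    if (length(rows) < k)
      stop("select_lvs: class '", cl, "' has fewer samples (", length(rows),
           ") than folds (", k, "); stratified folding impossible",
           call. = FALSE)
    fold[rows] <- rep_len(seq_len(k), length(rows))
  }
  fold
}

#' Choose the number of latent variables by K-fold cross-validation
#'
#' Runs stratified K-fold cross-validation over `n_lv = 1..lv_max` (folds
#' are assigned round-robin within each class in row order, so the procedure
#' is deterministic) and pools the out-of-fold predictions into one CV
#' confusion matrix per LV count. The chosen LV count is the smallest one
#' whose CV macro-F1 lies within `tau` percentage points of the maximum over
#' the grid — the smallest setting with stable performance, which guards
#' against overfitting from extra components.
#'
#' @param train A [spectrum_set()].
#' @param k Number of folds (>= 2), default 5.
#' @param lv_max Largest LV count tried, default 15 (capped by the data).
#' @param tau Plateau tolerance in macro-F1 percentage points, default 0.5.
#' @return List with `best_lv`, `cv_report` (data frame of macro-P/R/F1 per
#'   LV count) and `best_cv` (the report row at `best_lv`). Warns when the
#'   profile is still strictly increasing at `lv_max` (no plateau).
#' @export
select_lvs <- function(train, k = 5L, lv_max = 15L, tau = 0.5) {
  stopifnot(inherits(train, "spectrum_set"))
  k <- as.integer(k)
  if (k < 2L) stop("select_lvs: k must be >= 2", call. = FALSE)
  y <- factor(train$meta$group, GROUP_LEVELS)
  y <- droplevels(y)
  fold <- stratified_folds(as.character(y), k)
  lv_cap <- min(as.integer(lv_max), length(train$wavenumbers))

  pred <- matrix(NA_character_, n_spectra(train), lv_cap)
  for (f in seq_len(k)) {
    hold <- fold == f
    m <- fit_plsda(subset_spectra(train, !hold),
                   min(lv_cap, sum(!hold) - 1L))
    p <- predict_all_lv(m, subset_spectra(train, hold))
    if (ncol(p) < lv_cap)        # tiny fold cap; reuse the last component
      p <- p[, c(seq_len(ncol(p)), rep(ncol(p), lv_cap - ncol(p))),
             drop = FALSE]
    pred[hold, ] <- p
  }

  levels_y <- levels(y)
  cv <- data.frame(n_lv = seq_len(lv_cap), macro_P = NA_real_,
                   macro_R = NA_real_, macro_F1 = NA_real_)
  for (j in seq_len(lv_cap)) {
    cm <- table(truth = y,
                predicted = factor(pred[, j], levels_y))
    mm <- suppressWarnings(macro_metrics(unclass(cm)))
    cv$macro_P[j] <- mm$macro_P
    cv$macro_R[j] <- mm$macro_R
    cv$macro_F1[j] <- mm$macro_F1
  }
  best <- max(cv$macro_F1)
  best_lv <- cv$n_lv[which(cv$macro_F1 >= best - tau)[1]]
  if (best_lv == lv_cap && all(diff(cv$macro_F1) > 0))
    warning("select_lvs: CV macro-F1 still increasing at lv_max = ", lv_cap,
            " (no plateau)")
  list(best_lv = best_lv, cv_report = cv,
       best_cv = cv[cv$n_lv == best_lv, , drop = FALSE])
}

# Split, select LVs, fit and evaluate one dataset; one row of the Table-4
# style model comparison.
duration_model_row <- function(set, label, phase, k = 5L, lv_max = 15L,
                               tau = 0.5) {
  halves <- interleaved_split(set)
  sel <- select_lvs(halves$train, k = k, lv_max = lv_max, tau = tau)
  model <- fit_plsda(halves$train, sel$best_lv)
  rep <- evaluate_model(model, halves$test)
  data.frame(duration = label, phase = phase,
             n_samples = n_spectra(set), n_lv = sel$best_lv,
             mds = rep$mds,
             cv_P = sel$best_cv$macro_P, cv_R = sel$best_cv$macro_R,
             cv_F1 = sel$best_cv$macro_F1,
             test_P = rep$macro_P, test_R = rep$macro_R,
             test_F1 = rep$macro_F1,
             stringsAsFactors = FALSE)
}

#' Compare the classifier before and after data cleansing
#'
#' For the raw and the cleansed dataset alike, and for each stress duration
#' (plus optionally the pooled data), the spectra are split with
#' [interleaved_split()], the LV count is chosen on the training half with
#' [select_lvs()], a final model is fitted and evaluated on the held-out
#' test half. Deltas (cleaned minus raw) are reported for the LV count, the
#' misdiagnoses and the CV/test macro-F1.
#'
#' @param raw Preprocessed full [spectrum_set()].
#' @param cleaned The [cleanse()]d counterpart (same preprocessing).
#' @param k,lv_max,tau Passed to [select_lvs()].
#' @param durations Stress durations (h) to model separately.
#' @param include_pooled Also fit one model on all durations pooled.
#' @return A `comparison_report`: list with `models` (one row per dataset x
#'   duration: sample size, LVs, MDs, CV and test macro-P/R/F1) and `deltas`
#'   (per duration: `d_lv`, `d_mds`, `d_cv_f1`, `d_test_f1`).
#' @export
before_after_comparison <- function(raw, cleaned, k = 5L, lv_max = 15L,
                                    tau = 0.5,
                                    durations = c(24L, 72L, 120L, 168L),
                                    include_pooled = FALSE) {
  stopifnot(inherits(raw, "spectrum_set"), inherits(cleaned, "spectrum_set"))
  one_run <- function(set, label, phase)
    duration_model_row(set, label, phase, k = k, lv_max = lv_max, tau = tau)
  slice <- function(set, d) subset_spectra(set, set$meta$duration_h == d)

  rows <- list()
  for (d in durations) {
    rows[[paste0(d, "_raw")]] <- one_run(slice(raw, d), as.character(d),
                                         "raw")
    rows[[paste0(d, "_cleaned")]] <- one_run(slice(cleaned, d),
                                             as.character(d), "cleaned")
  }
  if (include_pooled) {
    rows[["pooled_raw"]] <- one_run(raw, "pooled", "raw")
    rows[["pooled_cleaned"]] <- one_run(cleaned, "pooled", "cleaned")
  }
  models <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

  deltas <- do.call(rbind, lapply(unique(models$duration), function(d) {
    a <- models[models$duration == d & models$phase == "raw", ]
    b <- models[models$duration == d & models$phase == "cleaned", ]
    data.frame(duration = d,
               d_lv = b$n_lv - a$n_lv, d_mds = b$mds - a$mds,
               d_cv_f1 = b$cv_F1 - a$cv_F1,
               d_test_f1 = b$test_F1 - a$test_F1,
               stringsAsFactors = FALSE)
  }))
  structure(list(models = models, deltas = deltas),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  print(x$models, digits = 4)
  cat("deltas (cleaned - raw):\n")
  print(x$deltas, digits = 4)
  invisible(x)
}
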