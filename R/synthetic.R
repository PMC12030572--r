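#' Default Raman peak library for synthetic leaf spectra
#'
#' The 20 characteristic peak centers (cm^-1) seen in cucumber-leaf Raman
#' spectra — pectin, cellulose, carotenoid, phenylpropanoid, protein and
#' aliphatic bands — with plausible relative base amplitudes (counts). The
#' strong carotenoid bands near 1155 and 1528 cm^-1 dominate.
#'
#' @return Data frame with columns `center` and `amplitude`.
#' @export
default_peak_library <- function() {
  data.frame(
    center = c(747, 917, 1005, 1048, 1080, 1117, 1155, 1185, 1218, 1265,
               1288, 1301, 1327, 1387, 1440, 1488, 1528, 1611, 1674, 3191),
    amplitude = c(320, 280, 520, 400, 380, 300, 900, 350, 330, 340,
                  420, 390, 460, 380, 620, 450, 1000, 520, 430, 360))
}

#' Configuration of the synthetic leaf-scan generator
#'
#' Bundles every generative parameter of [generate_dataset()]. Defaults
#' emulate the acquisition design the package targets: 3 leaves per
#' treatment group (CK/ND/PD/KD) per stress duration (24/72/120/168 h),
#' a 1.0 cm dot-matrix grid of roughly 30 in-leaf positions per leaf
#' (half-ellipse blade on one side of the main vein), a 200-3400 cm^-1 axis,
#' fluorescence-dominated baselines, group-dependent peak-intensity effects,
#' and region-localised anomalies that are strongest at 24 h and decay with
#' stress duration.
#'
#' @param seed Integer seed; the generator is reproducible per seed.
#' @param leaves_per_cell Leaves per group x duration cell.
#' @param wn_step Axis step (cm^-1) from 200 to 3400.
#' @param peaks Peak library data frame (`center`, `amplitude`).
#' @param peak_fwhm Gaussian peak full width at half maximum (cm^-1).
#' @param group_effects Named list (per non-control group) of named numeric
#'   vectors: multiplicative amplitude factors on designated peak centers.
#' @param baseline_amp Mean fluorescence baseline amplitude (counts); the
#'   baseline is a broad log-normal-shaped hump peaking near 400 cm^-1 with
#'   a long tail, mimicking the strong low-wavenumber fluorescence.
#' @param leaf_amp_sd,leaf_baseline_sd Log-scale SD of per-leaf peak
#'   amplitude and baseline amplitude variation.
#' @param position_amp_sd,position_baseline_sd Log-scale SD of
#'   position-to-position variation within a leaf.
#' @param noise_sd Additive per-channel acquisition noise SD (counts).
#' @param replicate_sd Per-acquisition noise SD (counts) of the replicate
#'   model; calibrated so a 30-acquisition stream keeps its minimum cosine
#'   similarity to the stream mean above the 0.991 stability benchmark.
#' @param grid_rows,grid_cols Integer vectors of candidate grid extents a
#'   leaf is drawn from (leaf-size variability).
#' @param anomaly_fractions Named vector: fraction of positions per region
#'   affected by an anomaly at 24 h.
#' @param anomaly_decay Named vector: multiplier of those fractions per
#'   stress duration (strongest at 24 h, decaying by 168 h).
#' @param anomaly_magnitude Log-scale SD of the multiplicative perturbation
#'   applied to a random subset of peak amplitudes at anomalous positions.
#' @param anomaly_peak_prob Probability that a given peak is perturbed at an
#'   anomalous position.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             leaves_per_cell = 3L,
                             wn_step = 4,
                             peaks = default_peak_library(),
                             peak_fwhm = 8,
                             group_effects = list(
                               ND = c("1005" = 0.72, "1155" = 0.72,
                                      "1528" = 0.62, "1611" = 0.80),
                               PD = c("747" = 0.85, "917" = 0.70,
                                      "1048" = 0.78, "1080" = 0.72),
                               KD = c("1327" = 1.32, "1387" = 1.40,
                                      "1440" = 1.28, "1674" = 1.20)),
                             baseline_amp = 4000,
                             leaf_amp_sd = 0.05,
                             leaf_baseline_sd = 0.15,
                             position_amp_sd = 0.05,
                             position_baseline_sd = 0.04,
                             noise_sd = 8,
                             replicate_sd = 8,
                             grid_rows = 8:10,
                             grid_cols = 4:5,
                             anomaly_fractions = c(margin = 0.50,
                                                   vein = 0.35,
                                                   base = 0.25,
                                                   interior = 0.03),
                             anomaly_decay = c("24" = 1, "72" = 0.35,
                                               "120" = 0.25, "168" = 0.12),
                             anomaly_magnitude = 0.55,
                             anomaly_peak_prob = 0.5) {
  stopifnot(is.numeric(seed), leaves_per_cell >= 1L, wn_step > 0,
            peak_fwhm > 0, baseline_amp > 0,
            all(anomaly_fractions >= 0), all(anomaly_fractions <= 1),
            all(anomaly_decay >= 0), all(anomaly_decay <= 1),
            anomaly_magnitude >= 0,
            anomaly_peak_prob >= 0, anomaly_peak_prob <= 1)
  cfg <- list(seed = as.integer(seed), leaves_per_cell = leaves_per_cell,
              wn_min = 200, wn_max = 3400, wn_step = wn_step,
              peaks = peaks, peak_fwhm = peak_fwhm,
              group_effects = group_effects,
              baseline_amp = baseline_amp,
              leaf_amp_sd = leaf_amp_sd, leaf_baseline_sd = leaf_baseline_sd,
              position_amp_sd = position_amp_sd,
              position_baseline_sd = position_baseline_sd,
              noise_sd = noise_sd, replicate_sd = replicate_sd,
              grid_rows = as.integer(grid_rows),
              grid_cols = as.integer(grid_cols),
              anomaly_fractions = anomaly_fractions,
              anomaly_decay = anomaly_decay,
              anomaly_magnitude = anomaly_magnitude,
              anomaly_peak_prob = anomaly_peak_prob)
  class(cfg) <- "synthetic_config"
  cfg
}

synthetic_axis <- function(cfg) seq(cfg$wn_min, cfg$wn_max, by = cfg$wn_step)

# Broad log-normal-shaped fluorescence hump peaking near 400 cm^-1.
fluorescence_profile <- function(wn) {
  u <- pmax(wn - 150, 1e-6) / 250
  exp(-log(u)^2 / (2 * 0.8^2))
}

gaussian_peaks <- function(wn, centers, amps, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  y <- numeric(length(wn))
  for (i in seq_along(centers))
    y <- y + amps[i] * exp(-(wn - centers[i])^2 / (2 * sigma^2))
  y
}

# Quarter-ellipse lattice on one side of the main vein: rows run from the
# leaf base (row 0, where the cordate blade is widest) to the tip, columns
# from the vein (col 0) outwards.
ellipse_leaf_cells <- function(n_rows, n_cols) {
  cells <- expand.grid(grid_row = 0:(n_rows - 1L), grid_col = 0:(n_cols - 1L))
  keep <- (cells$grid_row / n_rows)^2 +
    ((cells$grid_col + 0.5) / n_cols)^2 <= 1
  cells <- cells[keep, , drop = FALSE]
  cells <- cells[order(cells$grid_row, cells$grid_col), , drop = FALSE]
  rownames(cells) <- NULL
  cells
}

#' Generate a synthetic leaf-scan dataset
#'
#' Draws one dot-matrix Raman scan per leaf for every treatment group and
#' stress duration: each position's spectrum is
#' `fluorescence baseline + sum of Gaussian peaks x group effect x
#' (anomaly perturbation if flagged) + noise`. Anomalous positions receive a
#' multiplicative perturbation of a random subset of peak amplitudes plus a
#' local broad baseline bump — lowering their cosine similarity to the leaf
#' mean without changing the class identity of the leaf. Ground truth
#' records which positions were perturbed.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `set` (a raw [spectrum_set()]), `grids` (named list of
#'   [leaf_grid()]), and `truth` (data frame: `spectrum_id`, `leaf_id`,
#'   `group`, `duration_h`, `region`, `is_anomalous`).
#' @export
generate_dataset <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  wn <- synthetic_axis(cfg)
  centers <- cfg$peaks$center
  base_amp <- cfg$peaks$amplitude
  n_peaks <- length(centers)

  spectra <- list(); meta <- list(); truth <- list(); grids <- list()
  for (d in DURATION_LEVELS) {
    decay <- cfg$anomaly_decay[[as.character(d)]]
    for (g in GROUP_LEVELS) {
      eff <- rep(1, n_peaks)
      ge <- cfg$group_effects[[g]]
      if (!is.null(ge))
        eff[match(as.numeric(names(ge)), centers)] <- ge
      for (l in seq_len(cfg$leaves_per_cell)) {
        lid <- sprintf("%s_%dh_L%d", g, d, l)
        nr <- if (length(cfg$grid_rows) > 1L)
          sample(cfg$grid_rows, 1L) else cfg$grid_rows
        nc <- if (length(cfg$grid_cols) > 1L)
          sample(cfg$grid_cols, 1L) else cfg$grid_cols
        cells <- assign_regions(ellipse_leaf_cells(nr, nc))
        grids[[lid]] <- leaf_grid(lid, cells)

        leaf_amp <- base_amp * eff * exp(stats::rnorm(n_peaks, 0,
                                                      cfg$leaf_amp_sd))
        leaf_base <- cfg$baseline_amp * exp(stats::rnorm(1, 0,
                                                         cfg$leaf_baseline_sd))
        p_anom <- cfg$anomaly_fractions[cells$region] * decay
        anomalous <- stats::runif(nrow(cells)) < p_anom

        for (i in seq_len(nrow(cells))) {
          amp <- leaf_amp * exp(stats::rnorm(n_peaks, 0,
                                             cfg$position_amp_sd))
          bump <- 0
          if (anomalous[i]) {
            hit <- stats::runif(n_peaks) < cfg$anomaly_peak_prob
            mult <- ifelse(hit,
                           pmin(pmax(exp(stats::rnorm(
                             n_peaks, 0, cfg$anomaly_magnitude)),
                             0.25), 2.5),
                           1)
            amp <- amp * mult
            b_center <- stats::runif(1, 300, 1800)
            b_width <- stats::runif(1, 100, 300)
            b_height <- stats::runif(1, 0.10, 0.30) * leaf_base
            bump <- b_height * exp(-(wn - b_center)^2 / (2 * b_width^2))
          }
          pos_base <- leaf_base * exp(stats::rnorm(1, 0,
                                                   cfg$position_baseline_sd))
          y <- pos_base * fluorescence_profile(wn) +
            gaussian_peaks(wn, centers, amp, cfg$peak_fwhm) + bump
          if (cfg$noise_sd > 0)
            y <- y + stats::rnorm(length(wn), 0, cfg$noise_sd)
          sid <- sprintf("%s_r%d_c%d", lid, cells$grid_row[i],
                         cells$grid_col[i])
          spectra[[sid]] <- y
          meta[[sid]] <- data.frame(
            spectrum_id = sid, leaf_id = lid, group = g, duration_h = d,
            grid_row = cells$grid_row[i], grid_col = cells$grid_col[i],
            stringsAsFactors = FALSE)
          truth[[sid]] <- data.frame(
            spectrum_id = sid, leaf_id = lid, group = g, duration_h = d,
            region = cells$region[i], is_anomalous = anomalous[i],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  set <- spectrum_set(wn, do.call(rbind, spectra),
                      do.call(rbind, c(meta, list(make.row.names = FALSE))))
  list(set = set, grids = grids,
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}

#' Generate a replicate acquisition stream for one position
#'
#' Re-acquires one (anomaly-free, control-group) position `n` times under
#' the replicate noise model: each acquisition is the position's true
#' spectrum plus independent per-channel Gaussian noise of SD
#' `cfg$replicate_sd`. Used to emulate the instrument-repeatability
#' benchmark.
#'
#' @param cfg A [synthetic_config()].
#' @param position Integer position index; different positions have
#'   different (randomly drawn) true spectra.
#' @param n Number of acquisitions.
#' @param seed Seed for the stream; defaults to `cfg$seed + position`.
#' @return A [spectrum_set()] of `n` replicate spectra sharing one grid
#'   position, with a `replicate_id` metadata column.
#' @export
generate_replicate_stream <- function(cfg = synthetic_config(), position = 1L,
                                      n = 30L,
                                      seed = cfg$seed + as.integer(position)) {
  stopifnot(inherits(cfg, "synthetic_config"), n >= 1L)
  set.seed(seed)
  wn <- synthetic_axis(cfg)
  n_peaks <- nrow(cfg$peaks)
  amp <- cfg$peaks$amplitude *
    exp(stats::rnorm(n_peaks, 0, cfg$leaf_amp_sd)) *
    exp(stats::rnorm(n_peaks, 0, cfg$position_amp_sd))
  bamp <- cfg$baseline_amp * exp(stats::rnorm(1, 0, cfg$leaf_baseline_sd))
  truth <- bamp * fluorescence_profile(wn) +
    gaussian_peaks(wn, cfg$peaks$center, amp, cfg$peak_fwhm)

  mat <- matrix(rep(truth, each = n), nrow = n)
  if (cfg$replicate_sd > 0)
    mat <- mat + matrix(stats::rnorm(n * length(wn), 0, cfg$replicate_sd),
                        nrow = n)
  lid <- sprintf("REP_P%d", as.integer(position))
  meta <- data.frame(
    spectrum_id = sprintf("%s_a%02d", lid, seq_len(n)),
    leaf_id = lid, group = "CK", duration_h = 24L,
    grid_row = 0L, grid_col = 0L, replicate_id = seq_len(n),
    stringsAsFactors = FALSE)
  spectrum_set(wn, mat, meta)
}
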