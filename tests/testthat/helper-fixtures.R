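# Shared fixtures, built in code.

# A tiny hand-made set: two leaves, three positions each, 4-channel axis.
tiny_set <- function() {
  wn <- c(200, 400, 600, 800)
  mat <- rbind(c(1, 2, 3, 4),
               c(2, 4, 6, 8),
               c(1, 1, 1, 2),
               c(5, 4, 3, 2),
               c(5, 4, 3, 1),
               c(4, 5, 3, 2))
  meta <- data.frame(
    spectrum_id = paste0("s", 1:6),
    leaf_id = rep(c("A", "B"), each = 3),
    group = rep(c("CK", "ND"), each = 3),
    duration_h = rep(c(24L, 72L), each = 3),
    grid_row = c(0L, 0L, 1L, 0L, 0L, 1L),
    grid_col = c(0L, 1L, 0L, 0L, 1L, 0L),
    stringsAsFactors = FALSE)
  spectrum_set(wn, mat, meta)
}

tiny_grid <- function(leaf_id = "A") {
  leaf_grid(leaf_id, data.frame(grid_row = c(0L, 0L, 1L),
                                grid_col = c(0L, 1L, 0L),
                                region = c("vein", "margin", "base")))
}

# A random valid spectrum set for round-trip property tests.
random_set <- function(n_spectra = 4L, n_chan = 7L) {
  wn <- sort(stats::runif(n_chan, 200, 3400))
  mat <- matrix(stats::runif(n_spectra * n_chan, 0, 5000),
                nrow = n_spectra)
  meta <- data.frame(
    spectrum_id = paste0("sp", seq_len(n_spectra)),
    leaf_id = paste0("L", rep_len(1:2, n_spectra)),
    group = rep_len(c("CK", "ND", "PD", "KD"), n_spectra),
    duration_h = rep_len(c(24L, 72L), n_spectra),
    grid_row = rep_len(0:3, n_spectra),
    grid_col = seq_len(n_spectra) %/% 2L,
    stringsAsFactors = FALSE)
  spectrum_set(wn, mat, meta)
}

# Reduced-size generator config for unit tests (full design stays the
# default elsewhere).
small_cfg <- function(seed = 1L, ...) {
  synthetic_config(seed = seed, leaves_per_cell = 1L, ...)
}

# Independent sort-based type-7 quantile oracle.
quantile_oracle <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- min(lo + 1, n)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# A two-class, well-separated spectral dataset for classifier tests: class
# means differ in designated channels, Gaussian noise around them.
two_class_set <- function(n_per_class = 20L, n_chan = 30L, shift = 4,
                          channels = 5L, sd = 0.5) {
  n <- 2L * n_per_class
  mu <- matrix(0, 2, n_chan)
  mu[2, seq_len(channels)] <- shift
  lab <- rep(c("CK", "ND"), each = n_per_class)
  mat <- mu[rep(1:2, each = n_per_class), ] +
    matrix(stats::rnorm(n * n_chan, 0, sd), n)
  mat <- mat - min(mat)        # keep intensities non-negative
  meta <- data.frame(
    spectrum_id = paste0("x", seq_len(n)),
    leaf_id = paste0("L", seq_len(n)),
    group = lab, duration_h = 24L,
    grid_row = 0L, grid_col = seq_len(n),
    stringsAsFactors = FALSE)
  spectrum_set(seq(200, length.out = n_chan, by = 10), mat, meta)
}
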