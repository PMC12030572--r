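---
title: "Selecting reliable Raman sampling positions on leaves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting reliable Raman sampling positions on leaves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Raman spectra taken at different positions of the same leaf do not carry the
same information. Positions near the blade margin, the main veins and the
petiole end are biochemically atypical and noisy; a classifier of nutrient
status trained on spectra pooled over all positions inherits that noise.
`leafspot` implements a position-selection workflow for dot-matrix leaf
scans: score every sampled position by how similar its spectrum is to the
leaf's mean spectrum, flag and map the low-similarity positions, remove them,
and quantify what that cleansing buys a nutrient-deficiency classifier.

The intended design is a four-arm nutrient experiment — control (CK),
nitrogen- (ND), phosphorus- (PD) and potassium-deficient (KD) plants —
sampled at four stress durations (24, 72, 120, 168 h), with spectra acquired
through a perforated template at 1.0 cm pitch on one side of the main vein,
three acquisitions averaged per hole, over a 200–3400 cm⁻¹ axis.

## Similarity scoring

Spectra are treated as vectors and compared by cosine similarity,

$$\cos\theta = \frac{\sum_i A_i B_i}
  {\sqrt{\sum_i A_i^2}\,\sqrt{\sum_i B_i^2}},$$

which is independent of overall intensity scale — appropriate because
absolute Raman counts vary with focus and surface geometry. The reference
$B$ is the channel-wise mean spectrum of the position's own leaf
(`leaf_mean_spectrum()`); averaging damps position-specific noise, so the
mean is the best available stand-in for the leaf's overall composition.
Similarity is computed on *preprocessed* spectra (baseline-corrected,
normalized); for such non-negative vectors it lies in [0, 1].

Two flagging rules operate on the similarity distribution:

* **box-plot outliers** — values below the lower whisker fence
  $Q_1 - 1.5\,\mathrm{IQR}$ of the pooled population (`boxplot_outliers()`
  with `population = "all"`), used for the global anomaly tabulations;
* **below-quartile** — values strictly below $Q_1$, used per leaf by the
  cleansing step.

Quartiles use linear interpolation of the empirical distribution (R's
default type 7). The convention is exposed (`qtype`) because no single
convention is canonical across instruments and software; all internal
consistency tests compare against an independent sort-based oracle.

The 0.991 instrument-repeatability benchmark is treated as a *reference*
value for reporting (`repeatability_report()`), not a hard filter: it is the
level of similarity attributable to instrument stability alone, estimated
from repeated acquisition at a fixed position, and separates
instrument-level variation from tissue-level variation. In
`repeatability_report()` the reference spectrum is the mean over the full
replicate stream, a fixed reference, which guarantees that per-position
minima are non-increasing in the collection count (a minimum over a superset
cannot exceed the minimum over a subset).

## Preprocessing

Leaf Raman spectra sit on a strong, broad fluorescence background. The
baseline estimator is an iterative moving-average clip-smoother
(`fit_baseline()`): starting from the raw spectrum, each of `iterations`
passes replaces the running estimate by the pointwise minimum of itself and
its centred `window`-point moving average. Narrow peaks are averaged down
and clipped away; the broad background survives, so the final estimate hugs
the valleys under the peaks. Defaults are `window = 31` points and
`iterations = 5`, matching the acquisition protocol this package targets.

Numerical choices:

* **edges** — reflect padding (mirror without repeating the end point),
  avoiding the endpoint droop of a truncated window;
* **zero clipping** — the corrected spectrum is
  $\max(y - \hat b, 0)$, so all corrected curves sit on or above zero;
* **weak idempotence** — once the background is removed, a second pass
  changes the signal by under 5 % of the *raw* total intensity. Measured
  against the small corrected total the second pass can remove far more
  (zero-clipped noise positives and the shoulders of peak clusters), so the
  raw total is the meaningful scale for "the baseline was captured in one
  application";
* **the 200–700 cm⁻¹ region** — the fluorescence hump there is too sharp
  for a 31-point window and remains under-corrected. This mirrors real
  instrument behaviour; the region is retained by default and can be
  trimmed with `preprocess_spectra(range = c(700, 3400))`.

Normalization is per-spectrum min–max to [0, 1] by default (the convention
that makes per-curve ranges comparable in published preprocessing figures);
`vector_norm` (unit Euclidean norm) is offered and leaves cosine similarity
exactly unchanged.

## Cleansing and the classifier

`cleanse()` removes every spectrum whose similarity is *strictly* below the
lower quartile of its own leaf ("below the quartile" read strictly, so ties
at $Q_1$ are kept); with a continuous similarity distribution this removes
about 25 % per leaf. Leaves with fewer than 4 spectra pass through
uncleansed with a warning, because their quartile is unstable. Cleansing is
applied to all groups including the control. Leaf means are not recomputed
after exclusion (single-pass); an iterative variant would change little and
complicates the exclusion ledger.

The classifier is PLS-DA: a partial least squares regression of the spectra
onto the one-hot class matrix (fit via `mixOmics::plsda`, mean-centred,
unscaled — autoscaling would inflate empty noise channels), predicting by
the largest continuous class score with ties broken in class order
CK < ND < PD < KD. The latent-variable count is chosen by stratified K-fold
cross-validation (deterministic round-robin folds in row order; default
K = 5): the chosen count is the *smallest* whose pooled out-of-fold
macro-F1 lies within `tau = 0.5` percentage points of the grid maximum over
1..`lv_max` (default 15). This operationalizes "the smallest number of
components with stable performance" and guards against overfitting.

Train/test splitting is interleaved along the collection sequence (row
order), stratified within each group × duration cell: alternate spectra go
to training and test, so both halves span the acquisition sequence and all
classes. Evaluation reports the 4 × 4 confusion matrix, the number of
misdiagnoses (off-diagonal total) and macro-averaged precision, recall and
F1 in percent; a class never predicted contributes precision 0. CV metrics
are computed on the training half only, consistent with a held-out test
set.

`before_after_comparison()` runs the whole selection-and-evaluation chain
on the raw and the cleansed dataset, per stress duration, and reports the
paired metric deltas.

## The synthetic study design

No public leaf-scan dataset accompanies this workflow, so the package
carries a first-class generator (`generate_dataset()`) that emulates the
study conditions and provides ground truth for every stage. Each spectrum
is

> baseline + Σ Gaussian peaks × (group effect) × (anomaly perturbation,
> if flagged) + noise.

Design of the defaults (all tunable in `synthetic_config()`):

* **design** — 3 leaves per group × duration, 16 cells, matching the
  three-plants-per-timepoint sampling of the target experiment; axis
  200–3400 cm⁻¹ at 4 cm⁻¹ steps (801 channels, the instrument's resolution
  class).
* **leaf lattice** — a quarter-ellipse on one side of the main vein,
  widest at the base row, because cucumber blades are cordate; drawn grid
  extents of 8–10 rows × 4–5 columns give roughly 27–42 in-leaf positions
  per leaf ("about 30 acquisitions per leaf"). Regions are assigned
  deterministically: `margin` for cells with an off-leaf neighbour (vein-
  and petiole-side edges excluded), then `vein` (columns 0–1), then `base`
  (rows 0–1), then `interior`.
* **peaks** — the 20 characteristic leaf bands between 747 and 3191 cm⁻¹
  with Gaussian line shape (FWHM 8 cm⁻¹) and relative amplitudes dominated
  by the carotenoid bands near 1155 and 1528 cm⁻¹.
* **baseline** — a broad log-normal-shaped fluorescence hump peaking near
  400 cm⁻¹ with a long tail, amplitude ~4000 counts: fluorescence-dominated
  raw spectra, and a deliberately sharp low-wavenumber flank that exercises
  the under-corrected 200–700 cm⁻¹ behaviour.
* **group effects** — multiplicative shifts of 20–40 % on four designated
  peaks per deficiency (e.g. the carotenoid bands reduced under N
  deficiency). Sizes were fixed at design time so that anomaly-free data
  are cleanly separable (test macro-F1 ≥ 99 %): any classifier degradation
  observed on the full generator is then attributable to the injected
  anomalies, not to class overlap.
* **biological variation** — log-normal per-leaf (SD 0.05) and
  per-position (SD 0.05) peak-amplitude jitter plus baseline amplitude
  jitter; additive channel noise of SD 8 counts.
* **replicate model** — re-acquisitions add channel noise of SD 8 counts;
  calibrated at design time so that a 30-acquisition stream keeps its
  minimum preprocessed similarity to the stream mean above the 0.991
  benchmark (a 100-stream design check passed 100/100).
* **anomalies** — at an anomalous position a random half of the peaks is
  multiplied by log-normal factors (log-SD 0.55, clamped to [0.25, 2.5])
  and a broad local baseline bump is added. Affected fractions are
  region-dependent (margin 0.50 > vein 0.35 > base 0.25 ≫ interior 0.03)
  and decay with stress duration (× 1, 0.35, 0.25, 0.12 at 24, 72, 120,
  168 h), reproducing the early-stress instability and its spatial
  pattern. The perturbation lowers cosine similarity without changing the
  group label, which is what makes cleansing recover performance.

What the generator does *not* emulate: physically realistic Raman cross
sections, instrument transfer functions, cosmic-ray spikes, wavenumber-axis
drift between sessions, or spatial correlation of anomalies beyond region
membership. Passing tests therefore demonstrate that the pipeline's logic
and statistics behave as designed under the assumed noise structure — not
that any particular real crop will show the same effect sizes.

## Problem sizes and numerical tolerances in the test-suite

The unit tests run the generator mostly at 1 leaf per cell (~530 spectra);
the qualitative end-to-end checks use the full default design (48 leaves,
~1600 spectra) over 10 seeds for the cleansing-improvement comparison and
20 seeds for the spatial-enrichment pattern, sizes at which each check
completes in minutes while the binomial noise on the seed counts is small.
Floating-point identities (cosine anchors, unit norms) are asserted at
1e-12; text round-trips at 1e-9 (15 significant digits are written).

## Known limitations

* Region assignment is a deterministic lattice proxy; real leaves would
  need image-based segmentation to label margins and veins.
* The baseline window/iteration defaults follow the target protocol; very
  different axis resolutions require rescaling `window` (it is specified in
  points, not cm⁻¹).
* The quartile population for the heat maps is configurable (`per_leaf`
  default, pooled optional) because the pooled-vs-per-leaf choice genuinely
  changes which positions are shown; the cleansing step always uses the
  per-leaf population.
* `cleanse()` assumes one similarity row per spectrum; replicate-level
  cleansing (before averaging) is out of scope.
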