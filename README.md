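# leafspot

Where on a leaf should you point a Raman spectrometer?

Raman spectroscopy can diagnose crop nutrient deficiencies (nitrogen,
phosphorus, potassium) days before visible symptoms, but spectra taken near
a leaf's margins, main veins or base are unstable and unrepresentative of
the blade's overall composition — and they quietly degrade any classifier
trained on them. `leafspot` implements a position-selection workflow for
dot-matrix leaf scans, aimed at plant-phenotyping and chemometrics work:

1. **Score** every sampled position by the cosine similarity of its
   (preprocessed) spectrum to its leaf's mean spectrum,

   cos θ = Σᵢ AᵢBᵢ / (√Σᵢ Aᵢ² · √Σᵢ Bᵢ²);

2. **Flag** anomalous positions with the box-plot rule
   (below Q₁ − 1.5·IQR) and the below-lower-quartile rule;
3. **Map** the flags back onto the leaf grid and quantify region
   enrichment (margin / vein / base / interior);
4. **Cleanse** each leaf of its strictly-below-Q₁ positions;
5. **Evaluate** a PLS-DA classifier of CK / ND / PD / KD status — with
   interleaved train/test splitting, K-fold latent-variable selection and
   macro-P/R/F1 metrics — before and after cleansing.

Because no public dataset of this kind exists, the package ships a
first-class synthetic leaf-scan generator (fluorescence-dominated
baselines, the 20 characteristic leaf Raman bands, group-dependent peak
effects, region-localised anomalies strongest at 24 h of stress) that
provides ground truth for every stage. The supporting pieces — iterative
moving-average baseline correction, min–max / vector normalization,
instrument-repeatability reports, and the leaf N/P/K wet-chemistry
calculators — are included.

## Worked example

```r
library(leafspot)

sim <- generate_dataset(synthetic_config(seed = 1))
sim$set
#> <spectrum_set> 1619 spectra x 801 channels (200-3400 cm^-1)
#>   leaves: 48 | groups: CK/KD/ND/PD | durations (h): 24/72/120/168

pre  <- preprocess_spectra(sim$set)          # baseline + minmax
sims <- similarity_table(pre)                # cosine vs. leaf mean
flagged <- boxplot_outliers(sims, population = "all")
attr(flagged, "summary")
#>   population    n    min    max  mean      sd     q1 lower_fence
#> 1        all 1619 0.9023 0.9992 0.994 0.01228 0.9977      0.9964

cl <- cleanse(pre, sims, q = 0.25, population = "per_leaf")
cl
#> <cleansing_result> rule: similarity < per_leaf 0.25-quantile (type 7)
#>   1619 spectra -> 1215 kept (404 excluded, 25%)

at24 <- function(s) subset_spectra(s, s$meta$duration_h == 24)
before_after_comparison(at24(pre), at24(cl$kept), durations = 24)
#>   duration   phase n_samples n_lv mds  cv_P  cv_R cv_F1 test_P test_R test_F1
#> 1       24     raw       425    9  44 88.44 88.26 88.28  79.62  79.21   79.21
#> 2       24 cleaned       319    5   5 98.30 98.17 98.18  96.90  96.84   96.84
#> deltas (cleaned - raw):
#>   duration d_lv d_mds d_cv_f1 d_test_f1
#> 1       24   -4   -39   9.908     17.63
```

Reading the numbers: at 24 h of stress — before any visible symptoms —
the raw scan's low-similarity positions cost the classifier ~18 test
macro-F1 points. Removing each leaf's below-quartile quarter of positions
drops the chosen latent variables from 9 to 5 (a simpler, less overfit
model), cuts misdiagnoses from 44 to 5, and lifts test macro-F1 from 79 %
to 97 %. `run_pipeline(pipeline_config(seed = 1))` performs the same chain
end-to-end for all four durations and bundles validation, similarity
summaries, outlier tabulations, leaf maps, region enrichment, the
cleansing ledger and the model comparison into one report
(`write_run_report()` serialises it to JSON).

The spatial side:

```r
perleaf <- boxplot_outliers(sims, population = "per_leaf")
maps <- lapply(sim$grids, function(g) build_similarity_map(perleaf, g))
region_enrichment(maps)      # margin enrichment ~1.3, interior ~0.5
export_map(maps[[1]], "leaf1.png", "png_heatmap")
```

## Package layout

| | |
|---|---|
| `spectrum_set`, `leaf_grid` | containers: axis + intensity matrix + metadata; dot-matrix geometry with region labels |
| `read_spectra_table()` / `write_spectra_table()` | wide/long CSV dialects + metadata sidecar; `read_leaf_grids()` JSON |
| `preprocess_spectra()` | replicate averaging → iterative moving-average baseline (window 31, 5 iterations) → normalization |
| `similarity_table()`, `boxplot_outliers()`, `repeatability_report()` | cosine scoring and flagging |
| `build_similarity_map()`, `region_enrichment()`, `export_map()` | leaf heat maps, region statistics |
| `cleanse()` | per-leaf lower-quartile exclusion with ledger |
| `interleaved_split()`, `select_lvs()`, `fit_plsda()`, `evaluate_model()`, `before_after_comparison()` | classifier and its evaluation |
| `nitrogen_content()`, `phosphorus_content()`, `potassium_content()` | leaf N/P/K wet-chemistry formulas |
| `generate_dataset()`, `generate_replicate_stream()` | synthetic study design with ground truth |
| `run_pipeline()` | one-call orchestration, JSON report |

See `vignettes/position-selection.Rmd` for the methods account: model
assumptions, parameter defaults and why, generator design and calibration,
and known limitations.
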