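Package: leafspot
Title: Spatial Selection of Raman Sampling Positions on Plant Leaves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for choosing reliable Raman sampling positions on plant
    leaves from dot-matrix spectral scans. Every position's spectrum is scored
    by cosine similarity to its leaf's mean spectrum; low-similarity positions
    are flagged by box-plot rules, mapped onto the leaf grid, and removed by a
    per-leaf lower-quartile cleansing step. A PLS-DA nutrient-deficiency
    classifier (control vs. nitrogen-, phosphorus- and potassium-deficient
    groups) is evaluated before and after cleansing with macro precision,
    recall and F1. Includes the iterative moving-average baseline correction
    and normalization chain used upstream, leaf N/P/K content calculators, and
    a synthetic leaf-scan generator that provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    mixOmics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
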