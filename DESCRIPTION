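Package: hexiz
Title: Hexagonal-Grid Heterogeneity and Immunogradient Indicators for Digital Pathology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spatial analysis of immunohistochemistry cell detections by
    randomized hexagonal-grid subsampling. Computes intratumoral heterogeneity
    of Ki67 positivity via rank co-occurrence Haralick texture indicators
    (entropy as the headline biomarker), extracts the tumor-stroma interface
    zone from hexagon-level tissue composition, and derives CD8+ cell density
    gradient indicators (aspect means/SDs, immunodrop, center of mass).
    Includes synthetic tissue, cell, and survival-cohort generators, optimal
    cutoff dichotomization, univariate screening, multivariable Cox modeling
    with Harrell's concordance, and a combined prognostic score with risk
    groups for breast-cancer-specific survival.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    png,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
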