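Package: serumNMR
Title: Serum 1H-NMR Fingerprinting with OPLS-DA and Replicate-Aware Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A testable pipeline for one-dimensional 1H-NMR serum
    fingerprinting: a Lorentzian multiplet simulator driven by a serum
    metabolite library, spectral preprocessing (region exclusion, first-order
    baseline correction, two-stage correlation-optimised alignment,
    probabilistic quotient normalisation), moment- and PCA-based outlier
    screening, PCA and OPLS-DA with class-centroid centering for unbalanced
    classes, triplicate-preserving contiguous-block cross-validation with
    Bayesian classification thresholds and permutation testing, and
    discriminatory-variable selection by back-scaled loadings, VIP and
    selectivity ratio, plus cross-cohort biomarker overlap accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
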