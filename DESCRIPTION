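Package: mfdfc
Title: Multi-Frequency Dynamic Functional Connectivity Classification of
    Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-stage classification of case/control resting-state fMRI
    cohorts from frequency-resolved features. BOLD region-of-interest time
    series are decomposed into natural-logarithm-spaced frequency bands
    (Slow-5, Slow-4, and the conventional 0.01-0.08 Hz band) by zero-padded
    discrete Fourier transform; fractional amplitude of low-frequency
    fluctuations (fALFF) per region and band identifies discriminative
    regions by recursive feature elimination; sliding-window Pearson
    correlations among those regions form dynamic functional connectivity
    features; a grid-searched support vector machine with repeated
    cross-validation classifies the groups. Includes a seeded synthetic
    cohort generator with known ground truth so every stage is testable
    without imaging data, and a reader for preprocessed 4-D NIfTI volumes
    with an integer-labelled atlas.
License: MIT
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    pROC,
    stats,
    utils
Suggests:
    optparse,
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
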