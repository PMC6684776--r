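Package: crpfp
Title: Cysteine-Rich Peptide Fingerprinting for Herbal Authentication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A chemometrics toolkit for authenticating medicinal herbs from
    cysteine-rich peptide (CRP) MALDI-TOF MS fingerprints and UPLC
    chromatograms. Provides spectrum and fingerprint-matrix input/output,
    correlation optimized warping (COW) peak alignment with automatic
    reference and segment/slack selection, row and column preprocessing
    (standard normal variate, sum normalization, mean centering, blank
    subtraction), Kennard-Stone calibration/validation splitting, PCA with
    Hotelling's T-squared and Q-residual outlier detection, Ward
    hierarchical clustering, five supervised classifiers (PLS-DA, KNN,
    SIMCA, CART, SVM-DA) behind a uniform fit/predict contract with an
    "unassigned" outcome, confusion-matrix performance metrics,
    analytical-method validation statistics (calibration curves, LOD/LOQ,
    RSD, accuracy), and peptide-marker analytics (cysteine-spacing motifs,
    pairwise identity, peptide masses, in-silico proteolytic digestion).
    A synthetic fingerprint simulator makes every stage testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    e1071,
    Biostrings,
    jsonlite,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
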