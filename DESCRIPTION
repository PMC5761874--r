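Package: dynConn
Title: Dynamic Functional Connectivity via DCC-GARCH with Temporal and
    Spectral Feature Engineering
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates time-varying functional connectivity between pairs of
    BOLD-like network time courses with a two-step ARMA(2,2)-GARCH(1,1)
    dynamic conditional correlation (DCC) model, extracts seventeen temporal
    and spectral features of the resulting connectivity trajectory (Welch
    power spectra, spectral moments, entropy, flatness, crest, flux, slope,
    dominant frequency, low-frequency fluctuation amplitude), compares groups
    with bias-corrected and accelerated (BCa) bootstrap confidence intervals
    under false discovery rate control, and classifies subjects with repeated
    cross-validated random forests including conditional permutation variable
    importance. Sliding-window and static-connectivity baselines and a
    synthetic-cohort generator with known ground-truth dynamics are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    randomForest,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    boot,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: TimeCourse, Classification, StatisticalMethod, FunctionalGenomics
RoxygenNote: 7.3.3
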