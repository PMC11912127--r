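Package: ramanoid
Title: Raman Hyperspectral Classification of Cortical Organoid Maturation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Label-free Raman micro-spectroscopy workflow for staging
    cortical organoid maturation. Provides a synthetic hyperspectral
    data generator with organoid- and field-of-view-level random
    effects, the full spectral preprocessing chain (fingerprint
    extraction, Hampel despiking, Savitzky-Golay smoothing, iterative
    polynomial baseline subtraction, spatial binning, z-score and
    Frobenius normalization), principal component decomposition,
    random-forest stage and cell-line classification with stratified
    cross-validation and shadow-feature (Boruta-style) relevance
    selection, importance-weighted loading signatures, band-area
    quantification with Mann-Whitney group comparisons, and
    centroid-distance separability analysis with minimum detectable
    time-interval extrapolation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    randomForest,
    signal,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
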