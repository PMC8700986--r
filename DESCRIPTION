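Package: SpectraCP
Title: Local Changepoint Calibration for Spectral Phenotype Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to build and benchmark local partial least squares
    calibrations for mid-infrared spectral data. For each target sample
    (predictand), calibration neighbours are selected objectively by
    changepoint analysis (PELT or AMOC under SIC or MBIC penalties) of the
    sorted Mahalanobis distances between principal-component scores of the
    spectra. Local changepoint calibration is compared against a global
    partial least squares regression benchmark and against the classical
    LOCAL approach that ranks neighbours by Pearson correlation and uses
    fixed neighbour and factor counts. Includes spectral editing utilities
    (absorbance transform, high-noise region trimming, trait outlier
    removal, animal-level deduplication), a leave-one-out evaluation
    harness with edge-of-PC-space subset metrics, and a seeded synthetic
    spectra generator for homogeneous and clustered regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Rcpp,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
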