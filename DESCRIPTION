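Package: tdmoments
Title: Temporal Moment Analysis for Time-Domain Functional Near-Infrared
    Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing time-domain functional near-infrared
    spectroscopy (TD-fNIRS) data through the temporal moments of the
    distribution of times of flight (DTOF): moment computation with
    shot-noise and empirical covariance models, a layered-medium
    time-resolved photon Monte Carlo producing per-layer pathlength
    records and moment sensitivity lookup tables, generation of synthetic
    resting moment time series augmented with known hemodynamic response
    functions, and a family of response-recovery methods (continuous-wave
    block averaging and GLM with short-separation regression,
    covariance-weighted multidistance moment inversion, and a general
    linear model formulated directly on the moments) together with an
    evaluation and benchmarking harness.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
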