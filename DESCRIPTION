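Package: infantsway
Title: Center-of-Pressure Movement Analysis for Infant Spontaneous-Movement Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative assessment of infant spontaneous movements from
    force-plate center-of-pressure (COP) recordings. Provides reading of
    force-plate exports (raw force/moment channels or precomputed COP
    coordinates), Butterworth low-pass preprocessing with acclimation-window
    trimming, a battery of posturographic and nonlinear movement parameters
    (sway velocities, path lengths, 95% prediction ellipse, approximate
    entropy), anthropometric normalization, published prediction equations
    for classifying absent versus normal fidgety movements and for
    estimating the Motor Optimality Score-Revised (MOS-R), diagnostic
    accuracy evaluation with exact Clopper-Pearson intervals, and a
    synthetic COP simulator for end-to-end testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
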