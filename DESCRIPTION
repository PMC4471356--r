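Package: eegpipe
Title: Early-Stage EEG Preprocessing with Robust Referencing and
    Noisy-Channel Detection
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Early-stage preprocessing for continuous multichannel EEG:
    non-committal line-noise removal by multitaper harmonic regression
    with a Thomson F-test, a four-criterion noisy-channel detector
    (deviation, correlation, RANSAC predictability, high-frequency
    noisiness, plus NaN/no-data/dropout/low-SNR classes), two-phase
    robust average referencing with spherical-spline interpolation of
    bad channels, and windowed-statistics reporting.  Includes a
    synthetic bad-channel benchmark with ground truth for validating
    detection sensitivity and specificity, readers for EDF/BDF and raw
    matrix input, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
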