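Package: qrspeak
Title: Lightweight Fully-Convolutional QRS Complex Detection for ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects QRS complexes (heartbeats) in single- or dual-lead ECG
    signals with a small one-dimensional feature pyramid network trained by
    heat-map regression with ignore labels. Includes WFDB record and
    annotation input/output, canonical preprocessing (resampling to 250 Hz,
    0.5-35 Hz zero-phase Butterworth band-pass, per-lead z-scoring), a
    synthetic ECG and noise simulator for augmentation and fully
    self-contained testing, native model training with masked binary
    cross-entropy and Adam, non-maximum-suppression detection, and
    EC57-style beat-matching evaluation (sensitivity, precision, error
    rate, per-type false-negative rates, timing margins).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    generics,
    signal,
    yaml,
    optparse,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
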