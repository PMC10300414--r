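Package: sleepstager
Title: Sleep Stage Classification and Obstructive Sleep Apnea Screening
    from EEG Spectral Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated pipeline that converts multichannel sleep EEG
    into per-epoch relative power spectral density features (short-time
    Fourier transform, 1-s windows with 50% overlap, six frequency bands
    including max/mean operators targeting K-complexes and sleep
    spindles), classifies the five AASM sleep stages with support vector
    machine, k-nearest-neighbour and multilayer perceptron models
    selected by grid search, and screens for obstructive sleep apnea from
    stage-conditioned (REM/NREM) feature averages per subject.  Includes
    a repeated stratified cross-validation harness with one-way ANOVA and
    Bonferroni post-hoc comparisons, and a seeded synthetic
    polysomnography generator with stage-dependent spectra, K-complex and
    spindle transients, severity-dependent effects and oximetry so the
    whole pipeline is testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
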