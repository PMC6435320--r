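Package: pagfear
Title: Single-Unit and Behavioral Analysis of Probabilistic Pavlovian Fear Discrimination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing ventrolateral periaqueductal gray (vlPAG)
    single-unit recordings collected during three-cue Pavlovian fear
    discrimination, in which auditory cues predict foot shock with
    probability 1.00 (danger), 0.375 (uncertainty) or 0.00 (safety).
    Implements conditioned-suppression ratios on two timescales (whole-cue
    and 1 s intervals), waveform-and-rate k-means unit classification,
    peri-stimulus histograms with two Z-normalization schemes,
    sliding-window population departure analysis, firing-pattern
    categorization against a shuffle null, and trial-by-trial ordinary
    least squares regression of normalized firing on fear output and
    threat probability, including the nine-point threat-probability
    tuning sweep and post-cue interval regression. A synthetic session
    generator (randomized trial sequences, Poisson nose pokes inverted
    from target suppression ratios, inhomogeneous-Poisson spike trains
    with onset and ramping profiles) makes the full pipeline runnable and
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
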