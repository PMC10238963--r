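Package: hypnoval
Title: Validation of Consumer Sleep Trackers Against Polysomnography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for validating wearable sleep-stage output against
    manually scored polysomnography (PSG). Reads hypnograms and
    lights-off/lights-on markers from EDF+ annotation files or CSV, brings a
    1-minute 4-stage device hypnogram and a 30-second AASM-staged reference
    onto a common grid, vocabulary and time-in-bed window, derives standard
    per-night sleep summary parameters (TST, WASO, SOL, SE, stage minutes,
    awakenings), and quantifies agreement at the epoch level (2-way
    sleep/wake and 4-way stage confusion matrices, accuracy, sensitivity,
    specificity, Cohen's kappa; pooled and per participant) and at the
    parameter level (Shapiro-Wilk-gated paired t or Wilcoxon signed-rank
    tests, Cohen's d, Bland-Altman limits of agreement). Includes a
    Markov-chain synthetic cohort generator with a stage-conditional device
    error model so the full pipeline is testable without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
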