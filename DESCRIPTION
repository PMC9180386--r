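Package: somnoscore
Title: Autonomous Awake/Sleep Staging and Apnea/Hypopnea Scoring from Polysomnography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-part processing pipeline for overnight polysomnography (PSG)
    recordings. The first part classifies each 30-second AASM epoch as awake or
    asleep from accumulated alpha-band (8-13 Hz) EEG power and chin-EMG
    (24-45 Hz) power, with per-patient threshold calibration: a 100-point ROC
    scan yields the ROC-optimal threshold (ROT) and the largest threshold
    keeping false positives below a 10% cap (FPT), and a pooled linear
    regression of normalized FPT on ROT transfers the calibration to new
    recordings. The second part scores respiratory events from 5-second
    sliding amplitude envelopes of nasal-pressure flow: apneas (envelope below
    10% of the previous-epoch baseline for at least 10 s), hypopneas (10-70%
    of baseline with a >= 3-point SpO2 desaturation in the same epoch), and
    central-versus-obstructive classification from thoraco-abdominal effort
    suppression. Includes readers and writers for EDF and plain-text PSG
    formats, ADC-saturation artifact flagging, epoch-level evaluation metrics,
    a synthetic PSG generator with ground-truth hypnograms and injected
    events, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
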