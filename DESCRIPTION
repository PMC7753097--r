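Package: tvalpha
Title: Whole-Report TVA Modelling and EEG Alpha Power Attenuation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links visual processing speed, estimated from whole-report
    accuracy with the Theory of Visual Attention (TVA) exponential race
    model, to post-stimulus EEG alpha power attenuation measured as the
    log10 ratio of pre-stimulus to post-mask band power over a posterior
    region of interest. Provides the experimental-design tooling (display
    enumeration, balanced trial schedules, display-duration timing
    correction, gamer-group classification from questionnaire hours),
    maximum-likelihood estimation of the TVA processing-speed (C) and
    short-term-memory capacity (K) parameters, an EEG spectral pipeline
    (band-pass and notch filtering, common-average re-referencing,
    epoching, FFT power spectra on a 2 Hz grid, pre/post power ratios),
    the group-by-time-on-task inferential chain (one-tailed correlations,
    type II mixed ANOVAs with Greenhouse-Geisser correction and
    generalized eta squared, Cook's-distance screening, dummy-coded
    difference regression), and a synthetic-cohort generator producing
    behaviour, EEG, questionnaires, and timing logs with the statistical
    structure the analysis assumes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    jsonlite,
    signal,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
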