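Package: multirsvp
Title: Multi-Stream RSVP EEG Target Detection with Single-Trial P300 Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for multi-stream rapid serial
    visual presentation (RSVP) brain-computer interface experiments in which
    two or three time-delayed copies of an image stream are presented
    simultaneously so that each target elicits multiple P300 responses.
    Provides stimulus-schedule generation with a deterministic gaze model,
    a synthetic multi-channel EEG generator with repetition-dependent P300
    templates, a standard preprocessing chain (band-pass filtering,
    downsampling, epoching, baseline correction), hierarchical discriminant
    component analysis (HDCA) and stepwise linear discriminant analysis
    (SWLDA) single-trial classifiers, cross-stream interest-score fusion with
    cross-validated ROC/AUC evaluation, and the analytic target-miss
    probability model with Monte-Carlo validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
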