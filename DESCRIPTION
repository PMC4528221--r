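Package: brainswitch
Title: Detection of Attempted Movement from the EEG as a Brain Switch
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for detecting attempted hand movements from
    multichannel EEG in a cued brain-computer-interface design: an executable
    model of the session layout (conditions, sequences, blocks), a synthetic
    EEG/EMG generator with configurable event-related desynchronization and
    synchronization (ERD/ERS) structure, BrainVision reading and writing,
    epoch extraction, per-epoch linear detrending, a Perrin spherical-spline
    surface Laplacian, Welch band-power ERD/ERS features, a quadratically
    regularized linear logistic regression classifier with grid-searched
    regularization and stratified ten-fold cross-validation, cross-condition
    transfer (actual to attempted movement), binomial and group-level
    confidence intervals, and a sequential brain-switch detector with
    false-alarm calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
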