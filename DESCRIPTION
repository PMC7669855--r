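Package: caninevep
Title: Time-Resolved Decoding and Source Modelling of Canine Visual EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for event-related potentials recorded from
    dogs viewing faces, objects and scrambled images: synthetic multi-subject
    evoked-EEG simulation with 1/f background noise, preprocessing
    (band-pass filtering, general-linear-model trigger-leak removal,
    amplitude-based trial rejection, baseline correction, temporal binning),
    sliding-window repeated-measures ANOVA on evoked responses,
    time-resolved binary decoding with linear support-vector machines and
    permutation maximum-statistics family-wise error control, cross-subject
    aggregation of significant classifications, and equivalent current
    dipole fitting on a three-shell concentric-sphere head model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    e1071,
    data.table,
    jsonlite,
    yaml
Suggests:
    glmnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
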