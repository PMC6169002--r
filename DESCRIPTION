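Package: cmcoupling
Title: Cortico-Muscular Coupling Analysis by Mutual Information and
    Transfer Entropy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Nonparametric estimation of cortico-muscular coupling from
    paired local field potential (LFP) and electromyogram (EMG)
    recordings. Implements Kraskov-Stogbauer-Grassberger k-nearest-
    neighbor mutual information, bidirectional transfer entropy with
    Ragwitz-criterion delay embedding and prediction-time optimization,
    zero-phase signal preprocessing (notch, baseline removal, band-pass,
    rectification, trial segmentation), surrogate-data significance
    testing, repeated-measures ANOVA and correlation summaries, and a
    synthetic-data generator that emulates stimulus-locked LFP/EMG
    recordings under pulsed transcranial ultrasound stimulation so the
    whole pipeline is exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
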