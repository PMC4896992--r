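Package: cortstate
Title: Cortical State Classification from Local Field Potentials and
    State-Conditioned Haemodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies windows of cortical local field potential (LFP)
    recordings into synchronised and desynchronised brain states using a
    spectral-ratio coded-vector classifier: sliding-window FFT power in the
    five classical EEG bands is reduced to pairwise band differences, coded
    against automatically derived bounds, and matched to per-state model
    vectors by L1 distance. Includes an RMS power-threshold baseline
    classifier, state-conditioned partitioning and trial averaging of
    concurrent oxy-/deoxy-/total haemoglobin time series, a permutation
    (randomisation) control with a 1.5 IQR outlier rule, point-by-point
    accuracy scoring against reference labels, and a synthetic generator of
    ground-truth-labelled two-state LFP with coupled haemodynamics for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
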