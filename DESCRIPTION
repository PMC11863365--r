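Package: lipidsens
Title: Machine-Learning Prediction of Electrospray Ionization Sensitivity
    for Semiquantitative Lipidomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the relative electrospray ionization (ESI) sensitivity
    of lipids from 2D molecular descriptors computed from SMILES structures,
    and converts LC-MS peak areas into estimated concentrations
    (semiquantitative lipidomics). Implements per-lipid calibration-curve
    slope estimation with a linearity filter, relativization of slopes to a
    mode-specific reference internal standard, a support vector regression
    workflow with Box-Cox target transformation and recursive feature
    elimination trained over many random train/test iterations with
    median-model selection, Eq-1 style concentration prediction, surrogate
    one-point and lipid-class calibration baselines, a validation battery
    (percent-error summaries, precision, leave-class-out and extreme-size
    hold-outs, spike recovery), and a synthetic-data generator that emulates
    multi-level spiked calibration series for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    e1071,
    igraph,
    stats,
    utils
Suggests:
    MASS,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
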