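Package: MTForestNet
Title: Progressive Multitask Learning with Stacked Random Forests for
    Chemical Toxicity Prediction
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trains progressive multitask models in which layers of
    per-task random-forest classifiers are stacked: every layer beyond the
    first consumes the original molecular fingerprint concatenated with all
    tasks' class-probability scores from the previous layer, so that
    endpoints measured on distinct chemical collections exchange information
    through a shared score dimension. Includes chemical-space diagnostics
    (common-chemical percentage, average Tanimoto similarity, label
    correlation binning, fingerprint PCA), an embryonic zebrafish metric
    (EZ Metric) weighted-sum overall-toxicity score, downstream feature
    augmentation with predicted toxicity calls plus floating backward
    feature selection, and a synthetic multitask benchmark generator with
    controllable chemical-space overlap, task relatedness, and class
    imbalance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    ranger,
    jsonlite,
    yaml,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
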