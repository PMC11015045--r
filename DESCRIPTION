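Package: placecode
Title: Place-Cell and Population Coding Analysis for Head-Fixed Spatial Reward Learning
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis of neural population coding during head-fixed spatial
    reward learning on a circular treadmill belt. Provides behavioral event
    extraction (lick events, bouts, appetitive and consummatory onsets,
    lap segmentation, session success), place-cell classification by
    Skaggs spatial information against circular-shift permutation nulls,
    place-field geometry (Savitzky-Golay smoothed peak extraction,
    reliability, stability, circular center of mass, boundary-ratio
    permutation test, overdispersion), speed and lick tuning classification
    with false-discovery-rate control, a Poisson encoding model with
    grouped-feature shuffle significance defining conjunctive coding
    classes, and linear decoding of reward and anticipation zones with
    odd/even-lap cross-validation. A synthetic session generator with
    known per-neuron ground truth supports calibration and parameter
    recovery of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    signal,
    e1071,
    jsonlite,
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'utils-belt.R'
    'behavior.R'
    'decode.R'
    'glm.R'
    'io.R'
    'stats.R'
    'tuning.R'
    'spatial.R'
    'pipeline.R'
    'synthgen.R'
LinkingTo: Rcpp, RcppArmadillo
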