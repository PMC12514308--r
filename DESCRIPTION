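Package: ncreann
Title: Event-Related ECoG Analysis with Nonlinear Neural-Network Connectivity
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for event-related
    electrocorticography (ECoG) in a rodent two-tone auditory oddball
    paradigm. Provides a synthetic-data generator (oddball stimulus
    sequences, 3x3 epidural grid recordings with known evoked components
    and oscillatory bursts, nonlinear multivariate autoregressive
    ground-truth series, and alcohol-deprivation-effect drinking tables),
    FIR preprocessing with Kaiser-window design, epoching, artifact
    rejection and channel interpolation, ERP peak and peak-to-peak
    feature extraction, event-related spectral perturbation (ERSP) maps
    with per-band maxima, directed linear and nonlinear connectivity
    estimation by a one-hidden-layer perceptron fit to a nonlinear MVAR
    model (nCREANN) with time-shifted surrogate significance testing, and
    group/drinking statistics (mixed-design ANOVA, channelwise paired
    t-tests with FDR, Mann-Whitney with rank-biserial effect size,
    partial Spearman correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    data.table,
    jsonlite,
    yaml,
    randomForest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
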