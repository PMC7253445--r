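Package: scpm
Title: Seed Connectome-Based Predictive Modeling of Subjective States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds cross-validated, permutation-tested predictive models of
    subjective outcomes from seed-based background functional connectivity.
    From multi-run task fMRI timeseries the package computes stressor-modulated
    seed-to-voxel Fisher-z connectivity maps on confound- and task-regressed,
    bandpass-filtered residuals, defines group-level modulated clusters with
    permutation cluster-extent correction, and fits seed connectome-based
    predictive models (sCPM): correlation-threshold feature selection into
    positive and negative networks inside leave-one-out or k-fold
    cross-validation, linear network-strength models, nonparametric
    permutation significance, feature-consistency tests across model families
    with linked shuffles, and cross-seed cluster overlap. A synthetic-data
    module generates band-limited seed-coupled 4D timeseries, confounds, task
    designs and rating tables with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
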