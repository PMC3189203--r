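Package: ugdecode
Title: Real-Time fMRI Decoding of Ultimatum-Game Decisions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for predicting single-trial
    accept/reject decisions of an ultimatum-game responder from BOLD fMRI
    activity before the decision is revealed. Provides an ultimatum-game
    session generator, a synthetic 4D BOLD simulator with class-dependent
    region-of-interest activations, online feature extraction (per-trial ROI
    t-values), a sparse Bayesian (relevance vector machine) classifier with
    continuous per-trial retraining, permutation-based empirical guessing
    levels, offline whole-brain linear SVM classification with
    cross-validation and balanced resampling, and back-projection of
    classifier weights to voxel space with permutation significance and
    cluster-extent filtering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
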