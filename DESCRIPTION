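Package: dynstates
Title: Dynamic Functional Connectivity Brain-State Estimation, Dynamics and
    Clinical Prediction
Version: 0.1.0
Authors@R:
    person("Dynstates", "Maintainers", email = "maintainers@dynstates.org",
           role = c("aut", "cre"))
Description: Estimates transient functional-connectivity brain states from
    windowed multivariate time series by k-means clustering of Fisher
    z-transformed sliding-window correlation matrices, quantifies clustering
    instability by split resampling with Hungarian centroid matching,
    resolves the hierarchical relationship between adjacent state solutions
    via hybrid-state construction, computes dwell-time, persistence and
    transition-probability statistics of state sequences, fingerprints
    individuals from per-state connectivity profiles with rank-based
    permutation identification, performs covariate-residualized edgewise and
    network-level group comparisons with false-discovery-rate control, and
    predicts a binary clinical label from state-specific network strength
    using elastic-net logistic regression with leave-one-out
    cross-validation and permutation-tested AUC. Includes a synthetic cohort
    generator with planted latent-state structure, subject fingerprints,
    group effects and symptom signatures so that every stage can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
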