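Package: revlearn
Title: Reinforcement-Learning Models and Treatment-Response Classification
    for Probabilistic Reversal-Learning Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the behavioral-computational analysis of self-paced
    probabilistic reversal-learning experiments. Simulates the two-armed
    bandit task with performance-triggered contingency reversals, implements
    five trial-wise learning models (a surprise-weighted dynamic
    learning-rate model with and without choice stickiness, Pearce-Hall,
    a three-level hierarchical Gaussian filter, and a Kalman-filter gain
    adaptation variant), fits them hierarchically by empirical-Bayes
    expectation-maximization with Laplace posteriors, and compares them by
    integrated BIC. Also builds model-derived first-level fMRI design
    matrices (weighted reward-prediction-error regressors convolved with a
    double-gamma hemodynamic response) and provides the evaluation
    statistics for treatment-response classifiers: nested
    leave-one-subject-out cross-validation, the balanced-accuracy
    posterior, trapezoidal AUC with stratified bootstrap intervals, paired
    AUC comparison, elastic-net feature selection, and percentage-bend
    robust correlation. Synthetic-cohort generators with known ground
    truth support parameter- and model-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    e1071,
    glmnet,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC
Config/testthat/edition: 3
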