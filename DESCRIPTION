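Package: adaptcode
Title: Adaptive Sparse Population Coding with Belief-Driven Gain Modulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: A normative model of dynamic, attention-like modulation of a
    sparse-coding population of model V1 neurons. Sparse codes of natural-like
    image patches are passed through smooth shrinkage nonlinearities whose
    per-neuron thresholds are set by a Bayesian perceptual observer to
    minimize a cost trading task-inference error (symmetrized Kullback-Leibler
    divergence between posteriors under the compressed and full codes) against
    total neural activity. Includes synthetic stimulus generators, SparseNet
    style dictionary learning, observer models for object detection, target
    localization and orientation estimation, Rprop optimization of threshold
    tables over belief grids, closed-loop simulation with feedback-cost
    accounting, and analyses of the resulting code statistics (sparsity,
    noise correlations, tuning-curve modulation, gain dynamics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    utils,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
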