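Package: snnmarkov
Title: Symbolic Neural Network Covariate Models for Discrete-Time Markov
    Disease Progression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated covariate-model discovery for discrete-time multistate
    (Markov) disease-progression models. Small symbolic neural networks, whose
    activation units are arithmetic operations, map patient covariates to
    monthly transition probabilities; they are trained by maximum likelihood on
    exact, right-censored and interval-censored sojourn observations, and are
    iteratively pruned by parameter salience (squared parameter times the
    diagonal Hessian of the loss) until each transition mapping reads as a
    closed-form equation. Includes a five-state type 2 diabetes progression
    model as a worked reference, a cohort simulator with interval and right
    censoring, and an evaluation stack: Aalen-Johansen state occupancy,
    exponential-gamma censoring mixtures, visual predictive checks, Brier
    scores and Kullback-Leibler divergence on jackknife pseudo-observations.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    survival,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
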