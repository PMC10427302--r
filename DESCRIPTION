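Package: harshpref
Title: Bayesian Analysis of Facial Masculinity Preference Under Environmental-Harshness Priming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing two-alternative forced-choice experiments on
    women's preferences for masculinised versus feminised male faces after
    pathogen-prevalence or resource-scarcity priming. Implements the full
    study pipeline: long-format data model and validation, the participant and
    data-point exclusion cascade, scale scoring (Cronbach's alpha) and
    standardisation, and a joint Bayesian model combining a multilevel
    logistic choice submodel, cumulative-logit ordinal rating submodels with
    shared cut-points and cross-classified varying intercepts, and a
    scales-on-condition mediation submodel. Posterior sampling uses an
    adaptive Hamiltonian Monte Carlo backend with analytic gradients;
    summaries use 89% compatibility intervals, posterior contrasts and
    counterfactual choice-probability predictions. A synthetic-study
    generator draws complete datasets from the same generative model for
    testing and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    Matrix,
    tibble,
    dplyr,
    tidyr,
    rlang,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
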