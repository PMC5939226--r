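Package: aactask
Title: Simulation and Hierarchical Modelling of an Approach-Avoidance
    Conflict Gamble Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a two-condition bomb-gamble task used to study
    approach-avoidance conflict. Provides the 6 x 6 task space
    (environmental threat by activated tokens) with its objective
    probabilities, entropies and expected values; a seeded session
    simulator with stochastic bomb placement and exploration reveals; a
    softmax subjective-value choice model with loss-aversion, probability
    distortion, exploration-bonus and stage-2 bias parameters; hierarchical
    empirical-Bayes (type II maximum likelihood) fitting of subject cohorts
    with Laplace-approximated model evidence and iBIC model comparison; and
    synthetic-cohort generators for parameter-recovery and
    model-identification experiments. Trial-wise model latents (chosen,
    best-unchosen and value-difference regressors) are exported as tidy
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
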