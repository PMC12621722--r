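Package: pgrule
Title: Inferring Reinforcement Learning Rules from Trial-by-Trial Choice Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring the learning rules that drive de novo task
    acquisition from single-animal trial-by-trial choice data in
    two-alternative forced-choice experiments. The behavioural policy is a
    Bernoulli generalized linear model whose weights evolve under parametric
    policy-gradient (REINFORCE with reward baseline and weight decay) or
    temporal-difference learning rules with additive Gaussian noise. Model
    parameters are estimated by maximising a particle-filter marginal
    likelihood with held-out-trial masking; posterior weight and latent
    learning-rate trajectories come from particle smoothing, and parameter
    uncertainty from particle-marginal Metropolis-Hastings. Includes a
    synthetic-data simulator (stimulus curricula, session structure, cohort
    generation) and decompositions of inferred trajectories into learning and
    noise components, with learning-fraction statistics and cohort summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
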