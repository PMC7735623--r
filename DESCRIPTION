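Package: srdt
Title: Stochastic Representation Decision Theory for Risky Choice
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Models risky choice between lotteries as the absorption of a
    drifting Brownian particle on a star geometry: each outcome-probability
    pair becomes a branch whose length is set by the outcome's probability
    and whose drift is set by its utility.  The splitting probabilities
    yield non-separable, Luce-form choice probabilities in which
    probabilities and utilities are entangled.  Provides closed-form
    effective utilities for infinite and finite deliberation time, derived
    probability-weighting and transformed-utility curves, a lattice
    random-walk Monte Carlo oracle, scripted experiment pipelines (fourfold
    pattern of risk attitudes, stochastic dominance, time-pressure
    preference reversal, response times), and maximum-likelihood parameter
    fitting with synthetic-data generation and recovery checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
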