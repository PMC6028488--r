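Package: collrisk
Title: Collective-Risk Dilemma Games with Recurrent and Uncertain Losses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates multi-round collective-risk games in which players
    contribute from private endowments to lower the probability of stochastic
    wealth losses that may recur, strike at a known round, or strike at an
    unpredictable round. Provides exact expected payoffs by enumeration and
    fast Monte-Carlo play, Wright-Fisher evolutionary dynamics over
    threshold-based contribution strategies (including coevolving rich and
    poor populations under wealth and risk heterogeneity), closed-form best
    responses and evolutionarily stable states for the one-round
    heterogeneous linear-risk game, and seeded, sweep-oriented command-line
    tooling with tidy outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
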