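Package: cvoter
Title: The Concealed Voter Model: Hidden Opinions and Consensus Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and exact analysis of the Concealed Voter Model (CVM), a
    two-layer voter model on a complete graph in which each individual holds a
    public (external) and a private (internal) binary opinion. Individuals copy
    a random neighbour's public opinion at rate c, externalize their private
    opinion at rate e, and internalize their public opinion at rate i; agents
    whose layers disagree are "hypocrites". The package provides a fast
    count-based Gillespie engine and the literal agent-based reference
    algorithm, closed-form theory (the martingale strength of an opinion, mean
    consensus times, the slowdown factor relative to the basic voter model, the
    attractor of the mean-field flow, and hypocrite-equalization dynamics), an
    exact absorbing-Markov-chain solver for small groups, and ensemble
    experiment runners with confidence intervals that reproduce the model's
    predicted consensus probabilities, consensus times and equalization times.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
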