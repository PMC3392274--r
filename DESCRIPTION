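Package: inferrep
Title: Reputation-Inference Dynamics in Spatial Evolutionary Games
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo simulator for spatial prisoner's dilemma and snowdrift
    games in which strategy donors are selected by probabilistic reputation
    inference. Players on degree-4 interaction networks (periodic square
    lattice, random regular graph, Watts-Strogatz small world) accumulate
    reputation through cooperative acts; each player targets its
    highest-reputation neighbour as imitation source with a fixed personal
    inferring ability, falling back to a uniformly random neighbour otherwise,
    and adopts strategies via the Fermi rule. Includes experiment drivers for
    temptation sweeps, cooperator-extinction threshold estimation,
    noise-temptation phase diagrams and evaluation-factor sweeps, plus
    observables for donor-selection statistics, reputation-rank
    classification and cooperator cluster structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    ggplot2,
    readr,
    igraph,
    jsonlite,
    withr,
    rlang,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
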