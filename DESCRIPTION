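Package: condpunish
Title: Conditional Punishment in the Public Goods Game
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for the public goods game with
    pure cooperators, defectors, unconditional punishers, and conditional
    punishers whose punishing decision is triggered once the number of
    unconditional punishers in the group reaches a threshold. Covers three
    dynamical regimes: replicator dynamics in infinite well-mixed populations
    (with basin-of-attraction estimation on the strategy simplex and a
    closed-form stability analysis of the defector-punisher edge), stochastic
    dynamics in finite well-mixed populations (exact expected payoffs under
    hypergeometric group sampling, Fermi pairwise-comparison imitation,
    fixation probabilities, the rare-mutation embedded Markov chain, and
    individual-based mutation-selection simulation), and spatial Monte Carlo
    on a periodic square lattice with overlapping von Neumann groups.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
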