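Package: swarmforage
Title: Agent-Based Simulation of Individual and Collective Social Foraging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An agent-based model of social foraging on a periodic (toroidal)
    arena in which ten agents search for and jointly consume discrete targets.
    Agent movement combines a correlated random walk with optional flocking
    (alignment with visible neighbours) and distancing (a generalized
    Lennard-Jones spacing force), giving four movement regimes from fully
    independent to loosely coupled search. Includes visual chaining toward
    agents that have detected the target, shared target consumption, a
    pluggable controller hook for one agent slot, and a measurement suite
    (search and consumption times, grouping entropy of agents-in-view
    distributions, individual and collective area search rates, finding and
    consuming proportions), plus a seeded batch experiment runner and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
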