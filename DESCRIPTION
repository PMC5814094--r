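Package: holosim
Title: Network-Free Particle-Based Simulation of Multi-Subunit Signaling Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A particle-based stochastic reaction-diffusion simulator in which
    reactions are declared as site-level rules between binding sites of
    multi-subunit molecules and resolved at collision time by hash-table lookup,
    so that the combinatorially exploding species network of ring-shaped
    holoenzymes such as CaMKII never has to be expanded. Ships the
    Ca2+-calmodulin-CaMKII model family, stochastic voltage-gated Ca2+ channel
    influx with GHK-constrained single-channel currents, reaction-history
    pathway-flux analysis, ring-state (necklace) combinatorics, and independent
    ODE, stochastic-simulation-algorithm and exact Markov-chain oracles used to
    validate the engine.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    data.table,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
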