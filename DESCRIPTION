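Package: metamp
Title: Agent-Based Simulation of Beneficial-Mutant Spread in
    Metapopulation Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Stochastic agent-based simulation of a beneficial
    (antibiotic-resistant) mutant invading small metapopulations whose
    subpopulations are connected as star or well-mixed networks.  Each
    patch holds a fixed number of spaces; generations consist of death,
    birth, and migration phases, and dispersal follows weighted directed
    edges.  Provides graph builders and JSON serialization, scenario
    presets over migration rate, dispersal asymmetry, and serial-transfer
    bottlenecks, trajectory observables (metapopulation mutant fraction,
    time to majority, per-node spread order, ensemble averages,
    expected-migrant diagnostics), an exact Markov-chain oracle giving
    absorption (fixation) probabilities on tiny instances, and
    three-parameter logistic growth-curve fitting of spread trajectories
    by nonlinear least squares.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
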