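Package: perceptgg
Title: Evolutionary Dynamics of Perceptually Rational Agents in Public
    Goods Games
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for public goods games played
    by perceptually rational agents, i.e. agents that play the Nash
    equilibrium of the game they subjectively perceive while their
    perceptions of public-good cost and benefit, and their use of social
    information, evolve. Provides the single-group decision core
    (effective perceptions, rational play, objective and perceived
    payoffs), agent-based evolutionary dynamics on well-mixed and lattice
    populations with lineage ("species") tracking, exact discrete-time
    replicator-mutator dynamics for the binary-trait model, an
    evolutionary-stability analyzer for the eight binary rationality
    types, and observables: cooperation and sociality summaries,
    log-binned power-law tail fits of perceptual diversity, species
    lifespan and population-size distributions, Taylor's fluctuation
    scaling and spectral analysis of species richness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
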