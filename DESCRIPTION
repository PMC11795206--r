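Package: psmfkin
Title: Kinetic Network Analysis of Single-Molecule Fluorescence Visibility
    Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing binned visibility trajectories from
    polarization-sweep single-molecule fluorescence (PS-SMF) measurements of
    exciton-coupled dye dimer probes in DNA constructs. Estimates the
    probability distribution function and the two- and three-point
    time-correlation functions of the visibility, fits an N-state
    continuous-time Markov kinetic network with Gaussian macrostate emissions
    simultaneously to all three statistics, decomposes the model correlation
    functions into signed kinetic pathway terms, and converts fitted
    equilibrium populations and interconversion time constants into
    free-energy-surface parameters via the Boltzmann and Arrhenius relations.
    A stochastic simulator generates synthetic trajectory ensembles with the
    statistical structure the analysis assumes, so the entire pipeline can be
    validated without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    jsonlite,
    Matrix,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
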