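Package: latticeIPS
Title: Exact Stochastic Simulation of Interacting Particle Systems on Lattices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Exact (Gillespie-type) and approximate (tau-leaping) stochastic
    simulation of Interacting Particle Systems: continuous-time Markov models
    of discrete particles on lattices or arbitrary site graphs, with at most
    one particle per site (volume exclusion) and mass-action reactions between
    a particle and its immediate neighbors. Pairwise reactions are split into
    reaction channels by the number of adjacent reactants, probabilistically
    equivalent particles are grouped into sample classes in the style of the
    n-fold-way (Bortz-Kalos-Lebowitz) kinetic Monte Carlo method, and state
    updates after an event touch only the sites around the reaction, so the
    per-event cost is independent of lattice size. Ships example models of
    predator-prey dynamics, a rock-paper-scissors game, tumor-immune
    interaction under immunotherapy, and lipid (PUFA) oxidation with
    deuteration, together with brute-force validation oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'model.R'
    'enumeration.R'
    'state.R'
    'engine.R'
    'fixtures.R'
    'config.R'
    'lattice.R'
    'latticeIPS-package.R'
    'oracle.R'
    'trajectory.R'
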