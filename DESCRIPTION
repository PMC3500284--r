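Package: sseFold
Title: De Novo Protein Topology Assembly from Idealized Secondary Structure Elements
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembles protein topologies de novo by placing idealized
    alpha-helices and beta-strands as rigid bodies with a two-stage Monte
    Carlo Metropolis simulated-annealing search under a composite
    knowledge-based-style energy function. Builds consensus pools of
    predicted secondary structure elements from three-state per-residue
    predictions, closes chain breaks with cyclic coordinate descent loop
    building, and evaluates models with RMSD100, contact order, contact
    recovery and pool quality metrics. Includes a synthetic toy-protein
    generator for fully reproducible desk-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    bio3d,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
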