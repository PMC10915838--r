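Package: gencat
Title: Generality-Oriented Inverse Design of Asymmetric Organocatalysts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for fragment-based inverse design of asymmetric organocatalysts
    with substrate generality as the primary target, built around the Pictet-Spengler
    condensation of tryptamine derivatives and carbonyl compounds. Catalyst candidates
    are assembled from SMILES fragment libraries, enantioselectivity (ddG-dagger) and
    an activity descriptor (the relative free energy of the protonated
    tetrahydro-beta-carboline intermediate) are predicted with fingerprint-based
    tree-ensemble surrogate models, catalytic turnover is estimated from linear
    free-energy scaling relationships via the energy-span model and turnover-frequency
    volcano curves, diverse substrate panels are chosen by farthest point sampling of
    a PCA/t-SNE reaction map, and candidates are evolved with a genetic algorithm
    whose fitness hierarchically scalarizes median selectivity and activity and their
    spreads across the panel. A synthetic benchmark generator with planted additive
    landscapes and scaling relations makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    Matrix,
    Rtsne,
    jsonlite,
    stats,
    tools,
    utils,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
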