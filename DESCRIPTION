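Package: thpkin
Title: Kinetic Models and Enzyme Characterization for DHPAAS-Mediated
    Tetrahydropapaveroline Production
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying benzylisoquinoline alkaloid precursor
    production through the bifunctional insect enzyme
    3,4-dihydroxyphenylacetaldehyde synthase (DHPAAS).  Provides kinetic
    ODE models of three tetrahydropapaveroline (THP) pathway topologies
    with substrate feeding, product feedback inhibition, spontaneous
    Pictet-Spengler condensation and aldehyde drain; Monte-Carlo
    parameter-uncertainty ensembles with box statistics; Michaelis-Menten
    nonlinear fitting with iterative outlier elimination and
    profile-likelihood confidence intervals; bifunctional
    synthase/decarboxylase activity partitioning; molecular-mass, ion m/z
    and stoichiometric yield arithmetic; and active-site signature
    classification of AAAD-family protein sequences.  Includes seeded
    synthetic-data generators for closed-loop validation of every
    component.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    graphics,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
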