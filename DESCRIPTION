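Package: grooveflow
Title: Conformational, Geometric, Electrostatic and Kinetic Analysis of
    Lipid Scramblase Grooves
Version: 0.1.0
Authors@R:
    person("grooveflow", "developers", email = "grooveflow@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for the membrane-facing hydrophilic groove of
    TMEM16-family lipid scramblases. Reads PDB/PQR structures and simple
    trajectory formats; computes groove-state distance features, hydration
    counts and lipid-penetration fractions per frame; performs time-lagged
    independent component analysis (tICA) with microstate clustering and
    density landscapes; profiles pore radius along the permeation pathway
    with a sphere-probe method; solves the linearized Poisson-Boltzmann
    equation with a membrane-slab dielectric model; and models, simulates
    and fits dithionite scrambling-assay fluorescence kinetics and
    chloride-flux activity. Includes synthetic-data generators so every
    stage is testable without molecular dynamics or cryo-EM inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
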