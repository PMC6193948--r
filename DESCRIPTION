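Package: allokin
Title: Interacting-Sites Enzyme Kinetics, Model Selection and
    Part-of-the-Sites Binding Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing initial-velocity kinetics of oligomeric
    enzymes whose active sites interact. Fits the classical
    Michaelis-Menten rate law and a two-site interacting-sites
    (allosteric) rate law to replicate velocity data by weighted
    nonlinear least squares with multi-start search, and compares the
    nested models by an F-test. Includes a differential
    hydrogen/deuterium-exchange (HDX-MS) significance procedure with a
    pooled-SD confidence threshold, an analysis of per-site ligand
    occupancies across titration series of a hexameric enzyme
    (site-class filling order), and synthetic-data generators for all
    three data types so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    lhs
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
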