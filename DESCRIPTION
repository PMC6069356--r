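Package: chaforge
Title: Simulation-Assisted Design of Catalytic Hairpin Assembly Biosensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for simulation-assisted design and analysis of enzyme-free
    DNA biosensor circuits built on aptamer recognition and catalytic hairpin
    assembly (CHA). Provides pseudoknot-free nucleic-acid secondary-structure
    thermodynamics (loop decomposition, free energies, exhaustive ensembles,
    partition functions and minimum-free-energy prediction by dynamic
    programming), multi-strand test-tube equilibrium analysis (complex
    enumeration and convex mass-conservation solving), domain-level mass-action
    kinetics of a thrombin-triggered CHA circuit, G-quadruplex motif scanning,
    and downstream assay analytics (log-linear calibration, delta-F and F/F0
    metrics, 3-sigma/slope limit of detection), together with seeded synthetic
    readout generators and a command-line workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    deSolve,
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
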