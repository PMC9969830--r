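Package: netkin
Title: Mass-Action Kinetic Models from Protein Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Compiles curated signaling interaction networks (SIGNOR-dialect
    snapshots restricted to phosphorylation, dephosphorylation,
    ubiquitination, binding and transcriptional regulation) into elementary
    mass-action reaction systems, builds the corresponding ordinary
    differential equation model with a vectorized stoichiometry-matrix
    formulation, scores simulations against replicate multi-layer
    (protein / phosphoprotein / RNA) time-course data with a
    replicate-band-gated least-squares objective, and estimates kinetic
    parameters with a block-coordinate Nelder-Mead scheme that cycles over
    per-state-variable parameter groups. Includes a synthetic-fixture
    generator for triplicate multi-layer time courses so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
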