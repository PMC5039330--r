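Package: prodigal
Title: Individual-Based Simulation of Microbial Growth-Rate Evolution
    Under Environmental Enrichment
Version: 0.3.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-based simulator of cell-division-rate evolution in
    asexual microbial populations after environmental enrichment. Heritable
    growth rate and transmissible cellular damage jointly determine offspring
    viability: damage accrues with growth, is removed by repair that trades
    off linearly against growth allocation, is partially inherited by
    daughters, and raises the probability of offspring death through a Hill
    function. The package provides the deterministic damage-repair model, a
    fast stochastic generation engine, the canonical enrichment scenarios
    (reference, damage tolerance, cheap repair, damage reduction), replicate
    sweep orchestration over relaxation-time and Hill-steepness grids, and a
    command-line interface with YAML configuration and CSV/JSON output.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
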