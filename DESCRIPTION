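Package: riboforge
Title: Energy-Based Design of Multi-State Small RNA Regulatory Devices
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Automated sequence design of small RNA (sRNA) riboregulators
    that implement logic functions (YES, NOT, AND, OR) on gene expression.
    Gate specifications (truth tables, target secondary structures, fixed
    motifs such as the Shine-Dalgarno sequence) are compiled into an
    energy-based objective combining interaction kinetics (formation free
    energy plus a seed-length term) and structural fidelity (Hamming
    distance to target structures rescaled as free energy), which is then
    minimized by Monte Carlo simulated annealing with directed
    reverse-complement mutation operators. Includes a self-contained
    additive nearest-pair folding engine with exhaustive toy-scale oracles
    (reaction-coordinate landscapes, partition functions, base-pairing
    probabilities), an adapter for an external thermodynamic engine, a
    mass-action model of riboregulation with quasi-steady-state reduction,
    and synthetic mutant-library fixtures for validating the exponential
    free-energy model of regulatory fold change.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    deSolve,
    methods,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
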