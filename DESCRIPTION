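Package: ssakit
Title: Exact Stochastic Simulation of Reaction Networks with Explicit
    Per-Event Output
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Stochastic simulation of chemical reaction networks with
    explicit per-event output: every reaction occurrence is recorded with
    its time, the full copy-number state, the full propensity vector and
    the fired channel. Provides four solvers (Gillespie direct, first
    reaction, Gibson-Bruck next reaction, and adaptive tau-leaping with
    critical-reaction handling), a plain-text model description language
    and an SBML Level 2 subset reader, and the downstream statistics this
    output enables: event waiting-time distributions, holding-time
    weighted copy-number and propensity distributions, moments,
    autocorrelations and fixed-interval regridding. Includes explicit
    (gamma interdivision times, binomial partitioning) and implicit
    (first-order dilution) cell-division modeling, built-in case-study
    models of gene expression and single-molecule enzyme kinetics, and
    independent numeric oracles (truncated chemical master equation,
    phase-type waiting-time densities) for validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    tools,
    graphics,
    xml2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
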