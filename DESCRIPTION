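Package: cbswitch
Title: Coupled Bistable Switch Gene Circuits under Resource Competition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic and stochastic analysis of synthetic gene circuits
    built from two self-activating (bistable switch) modules hosted in
    Escherichia coli, with and without competition for shared gene-expression
    resources. Provides the family of two-variable circuit models (mutually
    activating cascading switches, separated switches, an aTc-tunable hybrid
    variant, and a two-strain division-of-labor variant), phase-plane analysis
    (nullclines, fixed points, separatrices), exact Gillespie simulation of the
    single-cell reaction network, chemical-master-equation stationary
    distributions and quasi-potential landscapes, inducer-dose fate maps, and a
    synthetic flow-cytometry population generator with gating and dose-response
    analysis, including a continuous two-segment piecewise-linear fit of
    reporter trade-off curves.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
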