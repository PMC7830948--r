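Package: plnopt
Title: Box-Behnken Design and Desirability Optimization for Nanoparticle
    Formulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for optimizing polymer-lipid hybrid nanoparticle
    formulations by response surface methodology: construction of
    three-factor Box-Behnken designs with coded/actual factor conversion,
    ordinary least squares fitting of the full quadratic response-surface
    polynomial, multi-response Derringer-Suich desirability optimization
    over the design cuboid with design-space (overlay) feasibility masks,
    and the standard formulation characterization arithmetic: encapsulation
    efficiency, cumulative in-vitro release with sampling-replacement
    correction, sink-condition checks, and comparative-Ct (2^-ddCt)
    relative gene expression. Includes seeded simulators for quadratic
    response surfaces, first-order dissolution sampling, and grouped qPCR
    Ct tables so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lhs
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
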