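Package: vakinetics
Title: Model-Based Compartmental Analysis of Whole-Body Vitamin A Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits plasma retinol tracer fraction-of-dose data to linear
    compartmental models of whole-body vitamin A metabolism with a pure
    absorption delay, by weighted nonlinear least squares with fractional-SD
    weights, optionally constrained by a dietary vitamin A intake observation
    under the steady-state assumption. Provides steady-state solutions
    (compartment masses, total body stores, disposal rate, days of stores,
    liver vitamin A concentration), tracer-theory parameters (transit,
    residence and recycling times and numbers), nested-model F-tests,
    population (geometric-mean composite) and per-subject analysis pipelines,
    and a synthetic-data generator for validating the whole workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
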