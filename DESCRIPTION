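Package: medeff
Title: Health-System Efficiency Benchmarking with Undesirable-Output
    Super-Efficiency SBM, Malmquist Decomposition and Panel Tobit
    Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Measures the allocation efficiency of medical and health
    resources across decision-making units (cities) observed over several
    years. Implements the slacks-based-measure (SBM) data envelopment
    analysis model with undesirable outputs, its super-efficiency variant
    that discriminates among frontier units, the CRS/VRS scale-efficiency
    decomposition, the Malmquist total-factor-productivity index with its
    efficiency-change and frontier-shift components, and censored-normal
    (Tobit) regression of efficiency on covariates, pooled and with
    unit-level random effects integrated by Gauss-Hermite quadrature.
    Ships a synthetic panel generator with a known production frontier for
    end-to-end validation, and reporting utilities that aggregate scores
    into province-level and city-level summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    statmod,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
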