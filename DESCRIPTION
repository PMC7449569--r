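Package: designdiag
Title: Declare, Simulate, and Diagnose Research Designs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Declares research designs as ordered, composable steps covering
    the model, inquiry, data strategy, and answer strategy; simulates them by
    Monte Carlo; and diagnoses them with summaries of diagnostic statistics
    (power, bias, RMSE, coverage, Type-S rate, exaggeration ratio, and
    others) with nonparametric bootstrap standard errors. Ships a catalogue
    of parameterized designs ranging from blocked experiments and regression
    discontinuity to Bayesian process tracing and crisp-set qualitative
    comparative analysis with Quine-McCluskey minimization, together with a
    command-line interface for simulation and diagnosis from YAML or JSON
    configuration files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    sandwich
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
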