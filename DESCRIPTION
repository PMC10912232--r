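Package: cscdelay
Title: Delayed Reaction-Diffusion Dynamics of Cancer Stem Cells with
    Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for a four-component delayed reaction-diffusion model of
    cancer stem cell (CSC) plasticity, in which differentiated cancer cells
    dedifferentiate back to the stem state at a rate driven by the delayed
    microRNA concentration. Provides closed-form equilibria and local
    stability conditions; a Hopf-bifurcation analysis of the delayed,
    diffusive linearization (characteristic-equation coefficients, purely
    imaginary crossings, delay branches, transversality, and the minimal
    critical delay per cancer parameter set); a two-dimensional
    method-of-lines simulator (classical RK4 with cubic Hermite history
    interpolation, zero-flux boundaries) for spatiotemporal pattern
    formation; and a fractionated-radiotherapy extension (linear-quadratic
    effective radiation with repair corrections, biologically effective
    dose, optimum dose per fraction, and Poisson tumor control
    probability). Includes a structured configuration format, scenario
    presets, delimited-text output writers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
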