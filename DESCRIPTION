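Package: viscofit
Title: Viscoelastic Parameterization of AFM Force Curves
Version: 0.1.0
Authors@R:
    person("viscofit", "developers", email = "viscofit@example.org",
           role = c("aut", "cre"))
Description: Fits generalized Maxwell and generalized Kelvin-Voigt material
    models to quasi-static atomic force microscopy (AFM) spherical-indentation
    force curves through the Lee-Radok hereditary integral, using seeded
    multistart bounded nonlinear least squares with an iterative
    term-introduction strategy. Derives multi-timescale storage modulus, loss
    modulus, and loss angle spectra with Student-t confidence bands, provides
    pseudo-elastic (Hertzian) baseline fits and population statistics, and
    includes a force-curve simulator so every stage is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    parallel,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
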