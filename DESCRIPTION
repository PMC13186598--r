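Package: slopebench
Title: Covariance-Structure Benchmarks for Regression Slopes in
    Sensorimotor Adaptation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying what between-subject regression slopes
    between implicit and explicit adaptation measures can and cannot say
    about the additivity assumption (total adaptation A = I + E). Provides
    closed-form expected slopes under subtractive and independent
    measurement, a shared-error generative model of implicit-explicit
    coupling, measurement-noise attenuation predictions, seeded
    synthetic-population generators, an OLS slope engine with
    benchmark-rejection decisions, Monte Carlo sweep and bootstrap
    experiment drivers, residual diagnostics, tidy CSV reporting, figure
    rendering, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    patchwork,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
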