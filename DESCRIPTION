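Package: ncis
Title: Non-Contact Impedance Spectroscopy of Electrolytes and Bacterial Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and fits non-contact impedance spectroscopy (NCIS)
    measurements of electrolytic conductivity cells and bacterial cultures.
    Provides the one-parameter parallel-RC equivalent-circuit model for
    conductivity sweeps with single-capacitance calibration, sigmoidal
    growth-curve fitting, a unified two-region (container-wall versus bulk)
    growth model, and a comparison pipeline relating impedance channels to
    optical density and optical reflection (normalisation, delay estimation,
    time-slot averaging and within-range linear regression). Seeded synthetic
    data generators emulate conductivity sweeps, multi-channel growth
    experiments and temperature jitter for testing and method exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
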