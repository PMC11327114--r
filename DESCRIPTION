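Package: envenomr
Title: Mechanistic Projection of Snakebite Envenoming Incidence Under
    Global Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a mechanistic model of snakebite envenoming
    incidence in which bites arise from a mass-action contact process
    between humans and venomous snakes, modulated by land cover,
    population density, species-specific contact and envenoming
    coefficients, and an intrinsic conditional autoregressive (CAR)
    spatial effect.  Provides Bayesian MCMC fitting with posterior
    predictive checks and DIC, delta-method climate bias correction with
    downscale validation, a CLUE-style annual land cover allocator,
    shape-preserving Hermite interpolation of decadal population
    projections, log-linear snake abundance index surfaces with
    niche-centroid distances, and an annual scenario projection engine
    (SSP/RCP style) with change statistics.  A synthetic-landscape
    generator emulates the statistical structure of the required inputs
    so the full pipeline runs and is tested end-to-end on simulated
    rasters.
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
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
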