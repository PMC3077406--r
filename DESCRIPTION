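Package: slantflow
Title: Bayesian Observer Models of Surface Slant from Actively Generated Optic Flow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for modeling the perception of planar surface slant from
    first-order optic flow during lateral head translation. Implements the
    generative flow model (deformation gradient 'def' of the velocity field),
    two Bayesian slant estimators evaluated on numerical grids -- an
    inverse-optics estimator that conditions on extra-retinal head-motion
    information and a retinal-only estimator whose posterior median follows
    k*sqrt(def) -- together with Monte Carlo simulations contrasting them, a
    synthetic psychophysics trial generator (active/passive viewing of virtual
    or physical surfaces), and the analysis layer (no-intercept sqrt(def)
    regressions, Vonesh-style agreement statistic, permutation test for a
    head-velocity effect, observed-versus-predicted comparison).
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    broom,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
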