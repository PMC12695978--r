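Package: isoshape
Title: Shape of Social-Isolation Effects from Penalized Additive Mixed Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to discern the shape of the relationship between a
    bounded exposure score (the six-item Lubben Social Network Scale,
    LSNS-6) and health outcomes in longitudinal cohort data: a synthetic
    cohort simulator with configurable ground-truth exposure-outcome
    shapes, measurement-level derivations (cognitive composites,
    ICV-adjusted hippocampal volume, OECD-equivalised income,
    socioeconomic weighting, clinical dichotomizations) with simplified
    multiple imputation by chained equations, a self-contained penalized
    additive mixed model engine (P-spline smooths, penalized IRLS for
    gaussian, Poisson and gamma families, random intercepts, GCV
    smoothing selection), smooth-versus-linear model comparison and shape
    classification, a gradient-by-frequency effect-share statistic, and a
    simulation power analysis for nonlinearity detection.
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
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mgcv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
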