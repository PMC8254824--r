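Package: cortage
Title: Dimensions of Longitudinal Cortical Change and Their Cognitive Correlates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates linear latent growth curves for regional brain volumes
    under full-information maximum likelihood with monotone attrition, extracts
    latent intercept and slope correlation matrices, projects them to the
    nearest correlation matrix, discovers their bifactor (general plus group)
    structure with minimum-residual factor extraction, oblimin rotation and the
    Schmid-Leiman transformation, confirms that structure with a constrained
    bifactor model, and couples the resulting factors of cortical change to
    cognitive decline and a binary genetic covariate with factor-of-curves
    growth models and false-discovery-rate control. Includes a synthetic cohort
    generator with known ground truth for recovery testing, emulating a
    narrow-age longitudinal ageing cohort measured at three waves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    lme4,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
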