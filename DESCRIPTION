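Package: clavage
Title: Adult Age Estimation from Degeneration of the Sternal End of the Clavicle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating age-at-death of mature adults (40+ years) from
    macroscopic degeneration of the sternal end of the clavicle. Implements
    ordinal scoring of surface topography, porosity and osteophyte formation,
    composite-score staging with per-sex 95% age intervals, a truncated-normal
    maximum-likelihood regression for age prediction with sex-dependent residual
    scale and AIC covariate selection, observer-agreement and symmetry
    statistics (weighted Cohen's kappa, Light's kappa with bootstrap standard
    errors, paired and two-proportion tests), a synthetic skeletal-collection
    generator for method validation, and a blind-test harness scoring interval
    coverage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
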