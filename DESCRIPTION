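Package: spraytrack
Title: Season-Long Assessment of Adulticide Spraying Against Aedes albopictus
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to assess a seasonal insecticide-spraying strategy against
    the tiger mosquito Aedes albopictus from sticky-trap surveillance and
    caged-mosquito experiments. Implements Henderson-Tilton single-treatment
    effectiveness for caged and wild mosquitoes, binomial and Poisson
    generalized linear mixed models of cage mortality and trap counts
    (distance decay, permethrin dose, water-leftover eco-climatic proxy),
    simulation-based validation of predicted cage mortality, and detection of
    treatment-induced divergence between treated and untreated site series
    via ARIMA pre-whitening, expanding-window correlations and change-point
    segmentation. A synthetic-data generator reproduces the statistical
    structure of the two-site monitoring design for testing and power
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
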