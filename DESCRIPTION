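Package: forestloss
Title: Field-Based Tree-Mortality Constraints on Projected Forest Carbon Fluxes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to screen repeated-census forest-plot records of biomass
    loss to tree mortality (LOSS), upscale plot-level LOSS to gridded maps
    with a random-forest model and bootstrap uncertainty, compare the maps
    with a multi-model ensemble of simulated mortality fluxes, and constrain
    the ensemble's projected net primary productivity (NPP), heterotrophic
    respiration (HR) and net carbon sink with either a conventional emergent
    constraint or per-model machine-learning surrogates evaluated at the
    observed LOSS. Includes a synthetic-data generator (covariate fields,
    clustered plot networks, and model ensembles with known LOSS couplings)
    so the whole pipeline can be exercised against a recoverable ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    ranger,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
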