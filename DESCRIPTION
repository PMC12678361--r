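Package: wheatnrec
Title: Nitrogen Topdressing Recommendation for Winter Wheat by Crop-Model
    Data Assimilation
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for recommending in-season nitrogen topdressing rates for
    winter wheat. Aboveground dry biomass (AGB) is estimated from multispectral
    reflectance through the two-band enhanced vegetation index (EVI2) and a
    hierarchical linear model with a growing-degree-day covariate; the
    estimates are assimilated into a daily process-based wheat growth surrogate
    by particle-swarm minimization of a relative-squared-error cost; the
    assimilated model is then run over a nitrogen grid to locate the
    economically optimal target yield and the lowest topdressing rate that
    attains it. Includes a seeded synthetic-data generator emulating
    multi-treatment field experiments, goodness-of-fit metrics, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
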