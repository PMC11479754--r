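Package: lansing
Title: Demographic Analysis of Parental-Age Effects on Offspring Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the demographic assessment of the Lansing Effect
    (shorter lifespans in offspring of older parents) from daily cohort
    census data. Fits exponential, Gompertz, Weibull and logistic mortality
    models to interval-censored integer lifespans by maximum likelihood,
    selects among them by small-sample-corrected AIC (AICc) and Akaike
    weights, and localizes between-group survival differences with a suite
    of eight joint two-group logistic models in which each parameter is
    either common to or distinct between groups. Includes randomization
    tests and stratified bootstrap confidence intervals for fitness-related
    life-history traits (lifespan, age at first reproduction, total
    offspring, and the intrinsic rate of increase from an individual-level
    Leslie matrix), bootstrap confidence bands for fitted survival curves,
    and a synthetic two-cohort generator emulating a duckweed longitudinal
    study for end-to-end rehearsal of the pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
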