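Package: lstpgm
Title: Latent State-Trait Piecewise Growth Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Specification, simulation, and maximum-likelihood estimation of
    single-indicator and multiple-indicator piecewise (linear-linear) growth
    models within the latent state-trait framework. Provides the model-implied
    moment structure for both model families, variance-component coefficients
    (consistency, occasion specificity, reliability), a calibrated synthetic
    data generator that hits target occasion specificity and reliability
    exactly, and a Monte Carlo harness for parameter-recovery studies
    summarised as relative bias.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
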