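Package: cfcpet
Title: Cardiopulmonary Exercise Test Analysis and Gaussian-Process
    Emulation for Cystic Fibrosis Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of breath-by-breath cardiopulmonary exercise test
    (CPET) ramp protocols in young patients with cystic fibrosis.
    Provides a validated tabular trace format, a seeded synthetic cohort
    generator with known ground truth, extraction of ventilatory and
    metabolic predictors (log-linear ventilation fits, baseline breathing
    pattern, oxygen uptake at a fixed ventilation), automated
    gas-exchange-threshold detection by continuous two-segment V-slope
    regression, a Gaussian-process emulator of the threshold with
    maximum-likelihood hyperparameters and leave-one-out cross-validation,
    principal-component characterisation of performance, and a mechanistic
    dead-space/alveolar-ventilation model with a compartmental
    cardiorespiratory ODE core.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
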