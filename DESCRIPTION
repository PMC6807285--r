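Package: aacsim
Title: Simulation and Analysis of Approach-Avoidance Conflict Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generative simulation and statistical analysis of a
    token-foraging approach-avoidance conflict game and a companion safe
    predator exposure task. Provides a discrete-hazard task simulator with
    configurable agent policies (including lesion-like policy
    perturbations), reconstruction of approach decisions and response
    latencies from event logs, linear mixed-effects condition-effect
    statistics with Greenhouse-Geisser correction, a distribution-free
    ordinal bootstrap test for single-case dissociations between patients
    ranked within their own control groups, and an exponentially modified
    Gaussian mixture model of predator exposure times compared via
    BIC-based log Bayes factors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
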