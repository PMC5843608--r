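Package: foragehazard
Title: Discrete-Time Hazard Models of Patch Leaving in Probabilistic Foraging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing nose-poke event logs from a two-port
    probabilistic foraging task in which reward probability decays
    exponentially within a patch. Implements the task's generative model and
    Bayesian next-reward inference over latent patch types, marginal value
    theorem optimality diagnostics, a discrete-time proportional-hazards
    model of patch leaving with reward resetting (construction, fitting,
    generative simulation, cross-validated comparison against an
    MVT-logistic alternative), photostimulation effect summaries, and
    poke-vigor (omission duty cycle) microstructure analyses. Includes a
    seeded synthetic-session generator used for parameter-recovery
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    rlang,
    tibble,
    readr,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
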