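Package: edsurge
Title: Discrete-Event Simulation of Emergency-Department Crowding Under
    Post-Earthquake Patient Surges
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates patient flow through a general emergency responsibility
    hospital (triage, consultation, laboratory/imaging and observation
    stations with finite resources) under normal operations and under
    post-earthquake surges of non-urgent (acuity level 3-5) patients.
    Computes daily per-acuity Crowdedness Index (mean door-to-doctor time
    over the advised maximum waiting time) and care Quality, summarises
    replicated scenario runs, and fits piecewise-linear response equations
    relating the patient growth ratio to the maximum Crowdedness Index.
    Includes scenario constructors for surge profiles, a reproducible
    seeded experiment runner, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
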