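Package: strokemdp
Title: Markov Decision Process Analysis of Stroke Convalescence Treatments
Version: 0.1.0
Authors@R:
    person("strokemdp", "developers", email = "strokemdp@example.org",
           role = c("aut", "cre"))
Description: Encodes longitudinal stroke-convalescence visit records into a
    finite Markov decision process (six-digit patient states, three-bit
    treatment-combination actions, neurological-impairment score differentials
    as rewards), estimates the empirical transition model from 7-day decision
    epochs, solves for the optimal treatment policy by Monte Carlo control
    with exploring starts, and reports stratified optimal-action frequency
    tables. Includes a seeded synthetic-cohort generator with a planted
    ground-truth optimal action for solver-recovery testing, plus an exact
    backward-induction oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
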