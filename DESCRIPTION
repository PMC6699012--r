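Package: appendcea
Title: Lifetime Cost-Effectiveness Modeling of Appendicitis Treatment
    Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic modeling of three management strategies for
    acute uncomplicated appendicitis (laparoscopic appendectomy, inpatient
    and outpatient antibiotic-only management): a 30-day decision tree
    feeding a lifetime monthly-cycle Markov cohort model with half-cycle
    correction and discounting, incremental cost-effectiveness analysis
    with dominance handling, one-way and two-way deterministic sensitivity
    analysis with threshold search, probabilistic sensitivity analysis
    with cost-effectiveness acceptability curves, scenario analyses, and
    an individual-level microsimulation used as an independent validation
    oracle for the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
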