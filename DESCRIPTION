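Package: afscreen
Title: Modeled Effectiveness of Atrial Fibrillation Screening in the Elderly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating community screening for untreated atrial
    fibrillation (AF) in people aged 65 and over. Implements a discrete-time
    annual-cycle Markov cohort model comparing anticoagulant-treated and
    untreated AF (life-years, quality-adjusted life-years, cumulative
    strokes), with a vectorised microsimulation cross-check; screening-cohort
    statistics (detection rates with exact binomial intervals, number needed
    to screen, stratified Fisher tests, interobserver kappa, CHADS2 and
    CHA2DS2-VASc scoring, diagnostic accuracy); a population-level projection
    of strokes preventable by treating screen-detected AF; and a seeded
    synthetic screening-cohort generator for fully reproducible analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
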