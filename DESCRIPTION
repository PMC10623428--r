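Package: metabodyn
Title: Glucose Dynamics Modelling and Metabolic Phenotyping for Rodent
    Diet-Intervention Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of long-term diet-intervention
    studies in rats: damped-oscillation modelling of glucose and insulin
    tolerance test curves with derived glycemic parameters and dysglycemia
    classification, metabolic phenotyping indices (HOMA-IR, normalized caloric
    intake, adipocyte size classes), variance-gated factorial statistics with
    Games-Howell and Dunn-Bonferroni post-hoc tests, and a MALDI imaging mass
    spectrometry strong-signal metabolite screen with adduct-mass annotation.
    Includes a synthetic cohort generator emulating a 4-intervention by 2-sex
    study design so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
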