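Package: gxdiet
Title: Gene-Diet Interaction Analysis for Dietary Quality Indices and
    Cardiometabolic Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for nutritional-epidemiology gene-diet interaction
    studies: FFQ-derived dietary quality scoring (the Fung DASH quintile
    score and the alcohol-free eight-point Trichopoulou Mediterranean Diet
    Score), derived cardiometabolic indices (Friedewald LDL-C, atherogenic
    index of plasma, HOMA-IR, QUICKI), NCEP ATP III metabolic syndrome and
    binary risk-flag classification, DASS-21 mental-health subscales,
    PCR-RFLP genotype calling with allele statistics and an exact
    Hardy-Weinberg test, sex-stratified ANCOVA genotype-by-diet-tertile
    interaction models with adjusted means and post-hoc contrasts,
    logistic and multinomial odds-ratio models under nested adjustment
    sets, and a configurable synthetic-cohort generator with plantable
    genotype main effects and interaction effects for calibration and
    power studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    nnet,
    emmeans,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
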