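Package: nafldtraj
Title: Non-HDL Cholesterol Trajectories, Incident NAFLD and Interaction
    Polygenic Risk Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for cohort studies of longitudinal
    non-HDL cholesterol and incident non-alcoholic fatty liver disease
    (NAFLD). Derives the NAFLD liver fat score phenotype and standard
    cardiometabolic covariates from biennial visit records, classifies
    participants into latent-class polynomial trajectory groups of
    non-HDL cholesterol fitted by EM with BIC model selection, computes
    person-time incidence and Cox proportional-hazards models for
    interval-detected NAFLD, runs genotype quality control, genotype
    principal components and stratified per-SNP logistic association
    scans, and builds an interaction polygenic risk score from the
    per-SNP difference in effect size between trajectory strata. A
    synthetic-cohort generator with known truth exercises every stage
    without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    knitr
Config/testthat/edition: 3
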