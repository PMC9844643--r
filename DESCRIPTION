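Package: gimets
Title: Joint Metabolic and Polygenic Risk Modelling of Gastrointestinal Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the joint effect of metabolic syndrome and
    polygenic risk on incident gastrointestinal (esophageal, gastric, and
    colorectal) cancer in prospective cohorts. Builds site-specific polygenic
    risk scores from GWAS summary statistics (harmonization against a
    reference panel, proxy substitution, LD clumping, dosage scoring) and
    combines them into an incidence-rate-weighted composite score; classifies
    metabolic syndrome by NCEP-ATP III criteria with an HbA1c surrogate for
    fasting glucose; fits Cox proportional-hazards models for joint
    genetic-by-metabolic risk stratification; and translates fitted models
    into 5-year absolute risks, absolute risk increases, and numbers-needed
    with bootstrap confidence intervals. A synthetic cohort generator with
    planted hazard effects makes the whole pipeline testable without access
    to individual-level biobank data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
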