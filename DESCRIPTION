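Package: cbcprs
Title: Polygenic Risk Scores and Contralateral Breast Cancer Risk in BRCA1/2
    Carriers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores the 313-variant breast-cancer polygenic risk score (PRS)
    from genotype dosages with effect-allele alignment and the
    population-control standardization contract, applies retrospective-cohort
    eligibility rules, and builds left-truncated time-at-risk intervals for
    contralateral breast cancer (CBC) in BRCA1/2 pathogenic-variant carriers.
    Fits country-stratified, family-clustered Cox models (continuous and
    percentile-category PRS, age interaction, subgroup fits) with Schoenfeld,
    spline-linearity and concordance diagnostics; imputes missing covariates
    by chained equations with estimate pooling; and converts a hazard ratio
    per SD into PRS-percentile-specific absolute CBC risk curves by
    constraining the baseline hazard to an external marginal incidence
    schedule. A family-structured cohort simulator with known generative
    parameters makes every stage testable without consortium data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    MASS,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
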