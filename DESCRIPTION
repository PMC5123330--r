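Package: gyntract
Title: Multi-Site Female Reproductive Tract Microbiome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Statistical workflow for multi-site 16S microbiome studies of
    the female reproductive tract with repeated samples per subject:
    alpha-diversity (observed richness, Shannon) with linear mixed models,
    Bray-Curtis and UniFrac beta diversity, block-permutation distance tests
    (organ correlation, shared taxa, cohort distance contrasts, PERMANOVA
    with subject-level label permutation), penalized quasi-likelihood
    overdispersed Poisson/binomial mixed models for differential abundance
    with Benjamini-Hochberg FDR, and presence/absence marker-panel
    evaluation (sensitivity, specificity, ROC/AUC). Includes a hierarchical
    synthetic-study generator and fixtures for printed study tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    vegan,
    nlme,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
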