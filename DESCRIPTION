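Package: sharedarch
Title: Shared Brain and Genetic Architecture Analysis for Mental Health
    and Physical Activity Phenotypes
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint phenotypic and genetic analysis of shared architecture
    between two phenotype blocks (here, mental health and physical
    activity) measured alongside resting-state brain network phenotypes.
    The phenotypic arm covers predictive mean matching imputation of
    questionnaire items, principal component reduction, and canonical
    correlation analysis with permutation inference on variates and
    loadings (simple and unique models).  The genetic arm covers LD score
    regression (SNP heritability, cross-trait genetic correlation with
    block-jackknife errors), a one-common-factor genomic structural
    equation model with CFI/SRMR fit indices, and latent causal variable
    analysis estimating the genetic causality proportion.  Synthetic
    generators produce cohorts with planted canonical structure and GWAS
    summary statistics obeying the LD score moment model, so every stage
    has a parameter-recovery test surface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
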