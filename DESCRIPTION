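Package: sfactor
Title: Comparing a Latent Genetic Factor with an Aggregate Ordinal Trait from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing a phenotypically aggregated ordinal trait with a
    latent common factor estimated from GWAS summary statistics of its component
    items. Implements multivariable LD-score regression (SNP-heritability, genetic
    correlation, genetic covariance with block-jackknife sampling covariance, and
    stratified annotation enrichment), a diagonally weighted least squares common
    factor model with chi-squared/CFI/AIC/SRMR fit statistics, Heywood-case
    correction and a per-SNP common-factor GWAS, a two-component effect-size
    mixture with projection of genome-wide-significant discoveries at future
    sample sizes, head-to-head difference tests with multiple-testing control,
    polygenic scoring of a target cohort with Nagelkerke pseudo-R2 association
    models, and a synthetic-data generator producing factor-structured
    multi-trait summary statistics, block LD references and individual-level
    cohorts so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
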