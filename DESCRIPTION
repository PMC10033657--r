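Package: ximpute
Title: Cross-Tissue Transcriptome Imputation from Blood Expression
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts region-specific brain gene-expression levels from
    peripheral-blood transcriptomes. Principal components of normalized
    blood expression are used as features in per-gene linear regression
    models trained on paired blood-brain cohorts; trained models are
    deployed on independent blood datasets to impute brain expression.
    Includes k-fold cross-validated accuracy estimation with a
    significance criterion (CV R-squared and Benjamini-Hochberg FDR),
    covariate-adjusted case-control differential-expression
    mega-analysis, concordance statistics for effect-size vectors with
    Fisher and Steiger z-tests, one-tailed Fisher's exact gene-set
    enrichment, and a latent-factor simulator of paired two-tissue
    cohorts with known cross-tissue shared variance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
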