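Package: gwasubtract
Title: GWAS-by-Subtraction for Proxy-Phenotype Cognitive Resilience
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the genetics of preserved processing speed
    (cognitive resilience) with proxy phenotypes: quadrant case-control
    phenotype construction from education years and age-corrected reaction
    time, per-variant logistic/linear association with covariates and
    conditional analysis, variant quality control, LD-score computation and
    LD-score regression (heritability, genetic covariance with block-jackknife
    sampling covariance), a Cholesky GWAS-by-subtraction model producing
    latent Resilience and EduYears summary statistics with effective sample
    sizes, two-stage LD clumping into independent significant SNPs, lead SNPs
    and merged genomic loci, and an exact binomial sign test for replication.
    Includes a synthetic-cohort generator with known genetic truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
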