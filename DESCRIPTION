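Package: gsbreed
Title: Genomic Selection Across Recurrent Breeding Cycles with Spatial
    Field-Trial Adjustment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-stage genomic selection analysis for outcrossing perennial
    breeding programs evaluated as unreplicated single plants on field grids.
    Provides genotyping-by-sequencing call filtering (read-depth, minor
    allele frequency, call-rate and genet-missingness rules), naive
    imputation, the VanRaden realized additive genomic relationship matrix,
    stage-1 REML mixed models with a genomic genetic effect and a separable
    AR1 x AR1 spatial residual per site, stage-2 kinship-based GBLUP with
    genomic heritability, cross-validation and across-cycle transferability
    evaluation with Fisher confidence intervals, and a seeded multi-cycle
    breeding-program simulator with full ground truth for parameter-recovery
    testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    lme4,
    yaml
Config/testthat/edition: 3
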