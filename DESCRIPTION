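Package: pgsdesk
Title: Polygenic Score Calculation from Imputed Genotypes with
    Ancestry-Aware Quality Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes polygenic scores (PGS) from imputed-genotype VCF files
    carrying per-sample dosages and per-variant imputation quality. Scoring
    files in the PGS Catalog format are merged into a single coordinate-sorted,
    tabix-indexed weight repository; scores are accumulated per genomic chunk
    with automatic strand-flip resolution, palindromic-variant exclusion,
    imputation-quality and missing-dosage filtering, and per-score coverage
    classification. A PCA-projection k-nearest-neighbour classifier assigns
    each sample one of seven super populations from a labelled reference panel
    and flags samples whose ancestry mismatches a score's source GWAS. A
    Balding-Nichols simulator generates structured reference panels, imputed
    study VCFs and score files with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    Rsamtools,
    SummarizedExperiment,
    VariantAnnotation,
    graphics,
    jsonlite,
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mgcv
Config/testthat/edition: 3
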