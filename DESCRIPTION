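Package: cnvgwas
Title: Copy-Number Variant Association Mapping from SNP-Array Intensities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for genome-wide association between copy-number
    variants (CNVs) and quantitative traits using SNP-array Log R Ratio
    intensities, modelled on dairy-cattle breeding applications. Provides
    GC-wave correction, multivariate (cross-sample pooled) recursive binary
    segmentation with a permutation stopping rule, three-state CNV
    genotyping, de-regression of predicted transmitting abilities,
    PCA-corrected additive linear-model association with permutation and
    Benjamini-Hochberg FDR control, pairwise linkage disequilibrium (D',
    r-squared) via two-locus EM with likelihood-based D' confidence
    intervals, Gabriel-criteria haplotype block partitioning, and
    classification of whether each trait-associated CNV is captured by
    neighbouring tag SNPs. A synthetic-cohort generator with block-LD
    genotypes, embedded CNV intensity shifts, GC waves and
    reliability-scaled phenotypes makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
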