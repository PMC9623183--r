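Package: caqtlkit
Title: Chromatin Accessibility QTL Mapping and Downstream Regulatory Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for chromatin accessibility quantitative
    trait locus (caQTL) analysis in tumor cohorts: genotype quality control
    with an exact Hardy-Weinberg test and principal-component covariates;
    fixed-width ATAC-seq peak construction with score-per-million
    normalization and iterative overlap removal; chromatin-state annotation
    and enrichment; cis-caQTL mapping with hidden-factor covariates and
    Benjamini-Hochberg FDR; caQTL-eQTL colocalization via Wakefield
    approximate Bayes factors; causal mediation of expression effects through
    accessibility with a nonparametric bootstrap; allele-specific
    transcription-factor motif disruption scoring with exact PWM match
    p-values; LD-based GWAS-locus overlap; and genotype-stratified survival
    scans under additive, dominant and recessive models. A synthetic-data
    module generates genotypes, accessibility, expression, survival and motif
    loci with planted effects so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
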