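Package: ppdscan
Title: Haplotype-Based Prioritization of Recessive Candidate Variants in
    Pedigreed Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Screens phased whole-genome variant data from small case-control
    pedigrees for candidate variants underlying recessive traits such as
    preaxial polydactyly. Implements GATK-style hard filtering and SNP-cluster
    flagging, cross-population extended haplotype homozygosity (XP-EHH)
    scanning, Weir-Cockerham fixation-index (FST) estimation in sliding
    windows for SNPs and INDELs, allelic case-control association, derived
    allele frequency and recessive genotype-phenotype concordance analysis,
    coding-effect annotation, and integration of all evidence tracks into a
    ranked candidate-gene report. A pedigree gene-dropping simulator with a
    planted causal haplotype makes the full pipeline testable without
    external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Rcpp,
    jsonlite,
    vcfR,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
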