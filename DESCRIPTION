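Package: uniprint
Title: Discovery of Putative Imprinted Genes from Uniparental Methylomes and Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for discovering putative imprinted genes from
    androgenetic, parthenogenetic and biparental stem-cell methylomes (RRBS
    per-CpG calls) and transcriptomes. Calls parent-of-origin differentially
    methylated promoter regions (TSS +/- 500 bp windows, CpG-level rank tests
    with Benjamini-Hochberg FDR), classifies imprinted-like expression between
    uniparental groups (TMM normalisation and a negative-binomial exact test),
    classifies allele-specific expression at heterozygous SNPs into monoallelic,
    partially monoallelic and biallelic classes, scans 1-kb windows for
    sperm-versus-oocyte germline DMRs by exact permutation test, distinguishes
    germline from secondary DMRs by persistence in uniparental cells, and
    integrates all evidence into a tiered candidate table with a cluster search
    around stringent hits. A seeded synthetic-data generator emulates the full
    study design (beta-binomial RRBS coverage, negative-binomial counts,
    binomial allele counts, gamete methylomes) so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
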