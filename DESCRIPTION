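Package: neosex
Title: Neo-Sex Chromosome Analysis from Sex-Stratified Resequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for avian neo-sex chromosome evolution from
    sex-stratified short-read resequencing data. Classifies assembly scaffolds
    as W-linked, Z-linked or autosomal from male/female coverage and
    heterozygosity, phases coding sequences into Z and W gametolog haplotypes
    from male/female genotypes, dates recombination suppression per gene by
    reading bootstrap-annotated gene-tree topology against a dated species
    phylogeny, estimates synonymous and nonsynonymous divergence (Nei-Gojobori
    counting) with group contrasts, and computes callable-site-corrected
    windowed nucleotide diversity. A seeded synthetic-data generator emulates
    the statistical structure of every input so each stage is testable with
    known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    stats,
    utils,
    yaml
Suggests:
    Biostrings,
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
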