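Package: salmonsnp
Title: Multi-Caller Consensus SNP Filtering and Diagnostic Marker
    Discovery for Atlantic Salmon Resequencing Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale re-implementation of a SNP-database
    construction pipeline for North American Atlantic salmon whole-genome
    resequencing panels. Reads per-caller VCF call sets (freebayes,
    mpileup, GATK style), applies a six-step filtering cascade
    (bi-allelic SNPs, indel proximity, variant quality, repeat masking,
    excess site depth, per-sample genotype re-calling from allele depths
    with a missingness cap) followed by removal of putative paralogous
    sequence variants via doubled-haploid controls, intersects the three
    filtered call sets with Venn accounting, computes minor-allele
    frequency spectra, per-strain polymorphism and heterozygosity
    summaries, per-site Weir-Cockerham Fst, a tiered panel of
    continent-diagnostic fixed-difference markers, and an LD-pruned
    bootstrapped neighbor-joining strain phylogeny. Includes a
    synthetic-data generator with full ground truth (population
    structure, PSV artifacts, repeat intervals, caller noise) that
    drives recovery tests for every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    GenomicRanges,
    IRanges,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
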