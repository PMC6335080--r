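Package: polycane
Title: Dosage-Aware Population Genomics for Highly Polyploid Germplasm Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-genomic analysis of highly polyploid crop
    germplasm (sugarcane-like panels) genotyped by deep target-enrichment
    sequencing. Calls integer allele dosages from per-sample allele depths by
    binomial maximum likelihood with a two-level confidence filter, discovers
    species-diagnostic markers between progenitor panels and estimates hybrid
    genome composition, computes dosage-based diversity (pi), Nei Fst,
    genetic distances, neighbour-joining trees and coding-effect summaries
    (Ti/Tv, N/S), measures linkage-disequilibrium decay, scans for selective
    sweeps with a population-branch statistic over SNP windows and for
    domestication genes with per-gene pi ratios, and performs latent-factor
    environmental association with multi-run z-score combination and genomic
    control. Includes a synthetic polyploid cohort simulator with known truth
    (Balding-Nichols progenitors, mosaic hybrids, negative-binomial read
    depths) so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    ape,
    vcfR,
    yaml,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
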