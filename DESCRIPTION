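Package: abbascan
Title: Windowed ABBA-BABA Introgression Scans for Four-Taxon Genome Comparisons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects genomic introgression between non-sister taxa in a
    four-taxon quartet (P1, P2, P3, outgroup) from per-site derived-allele
    frequencies. Implements frequency-weighted ABBA/BABA site counting,
    windowed Patterson's D with a block-jackknife z-test, the f_d
    admixture-fraction statistic, and absolute sequence divergence (d_xy)
    screening to separate introgression from incomplete lineage sorting.
    A three-stage filter cascade (D significance, top-decile f_d retention,
    significantly reduced d_xy) yields introgressed regions, which can be
    annotated against GFF3 gene models. Includes a deterministic four-taxon
    genome simulator with tunable topology-discordance noise and planted
    donor-to-recipient introgression tracts, so every stage of the pipeline
    is testable against known truth. Readers accept VCF, four-row aligned
    FASTA, and a simple tabular SNP format.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    vcfR,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
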