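Package: ssrscape
Title: Genome-Wide Microsatellite Mining, Landscape Characterization and
    Marker Polymorphism Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects perfect microsatellites (simple sequence repeats, SSRs)
    of unit length 2-6 bp in genome assemblies using MISA-style repeat-count
    thresholds, merges near-adjacent loci into compound SSRs, and classifies
    every repeat into its canonical motif class under cyclic rotation and
    reverse complementation.  Summarizes the SSR landscape per chromosome and
    genome (frequency in loci/Mb, density in bp/Mb, motif rankings,
    repeat-number spectra, size correlations), assigns loci to exonic,
    intronic, or intergenic space from GFF3 annotation, screens candidate SSR
    markers against primer design constraints, and computes per-locus
    polymorphism statistics (Na, Ne, Ho, unbiased He, Shannon's I, PIC) from
    genotype tables.  Includes a seeded synthetic-genome simulator that plants
    SSRs with a truth table so every pipeline stage is verifiable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
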