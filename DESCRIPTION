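Package: plastkit
Title: Comparative Plastid Genome and Transcriptome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative analysis of plastid (chloroplast) genomes
    and strand-specific plastid transcriptomes. Genome level: inverted-repeat
    boundary detection and quadripartite partitioning, pairwise substitution
    and indel distances on whole-plastome alignments, microsatellite (SSR)
    discovery with MISA-style thresholds and cross-genome SSR polymorphism,
    synonymous/non-synonymous classification of segregating sites in coding
    genes, and pairwise Ka/Ks by the Nei-Gojobori method. Phylogenetic input
    preparation: inverted-repeat removal, homopolymer masking, codon-aware
    CDS concatenation with partition export, and simple indel coding of gap
    characters. Transcriptome level: strand separation of paired-end
    alignments, filtering of reads derived from plastid-like insertions in
    mitochondrial genomes, per-base depth of coverage, per-feature TPM,
    antisense transcript detection, and discovery, quantification and
    cross-taxon conservation classification of C-to-U RNA editing sites,
    with group comparisons between sexes or haplotypes. A synthetic-data
    generator produces annotated toy plastomes, haplotype variants and
    stranded paired-end reads with planted editing so every stage can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
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
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
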