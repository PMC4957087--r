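Package: mitoscan
Title: Comparative Feature Analysis of Plant Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the comparative annotation-level analysis of plant
    mitochondrial genomes: identification and classification of C-to-U and
    U-to-C RNA-editing sites from genomic DNA versus cDNA comparisons,
    relative synonymous codon usage (RSCU) and codon third-position
    composition, detection of long direct and inverted repeats and perfect
    microsatellites (SSRs), detection of chloroplast-derived fragments
    (mitochondrial plastid DNA, MTPT) in a gene-masked genome with
    cross-species homolog scoring, simplified collinear gene-cluster
    detection between two gene orders, and genome summary statistics.
    Includes a deterministic synthetic-genome generator that plants
    ground-truth edits, fragments, repeats and SSR loci for end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    BiocGenerics,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
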