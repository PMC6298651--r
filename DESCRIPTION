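Package: cnvevo
Title: Copy-Number Variant Dynamics, Breakpoints and Lineages in Experimental Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying copy-number variant (CNV) dynamics and formation
    mechanisms in evolving microbial populations. Includes a synthetic-data
    generator (annotated genomes, CNV-bearing mutants with ground-truth
    junctions, paired-end reads and junction-aware alignments, chemostat
    selection trajectories, flow-cytometry events, barcoded lineage time
    courses); flow-cytometry based quantification of CNV subpopulations and
    their dynamics statistics (T_up, S_up, competitive fitness); read-depth CNV
    discovery with rule-based boundary refinement and a two-pass genome-wide
    scan; nucleotide-resolution breakpoint calling from split and discordant
    reads with contig assembly and interrupted inverted-repeat detection;
    rule-based CNV mechanism classification (ODIRA, NAHR, aneuploidy,
    translocation); barcode lineage tracking with sort-purity correction; and
    variant post-filtering with effect-class summaries.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
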