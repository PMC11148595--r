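Package: viroscreen
Title: Tiered Viral Metagenome Read Classification and Annotation Tables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale, fully testable implementation of the computational
    core of a tiered viral-metagenomics annotation workflow: read dereplication
    into representative sequences with per-sample count bookkeeping (seqtable),
    a two-stage amino-acid then nucleotide classification with confirmatory
    multikingdom cross-checks, lowest-common-ancestor taxonomy with top-hit
    reversion for root-degenerate assignments, Baltimore classification joins,
    viral-aware host-genome masking, contig abundance tables with RPKM/FPKM/SPM
    normalization, and a unified per-representative annotation table
    (bigtable). Alignment is pluggable: standard BLAST-tabular (m8) hit tables
    from external aligners are consumed directly, and a built-in naive
    seed-and-extend aligner plus synthetic community generators make every
    stage exercisable offline on toy fixtures with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    IRanges,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
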