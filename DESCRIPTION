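Package: top2dsb
Title: Quantification of TOP2-Mediated DNA Double-Strand Breaks from END-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of END-seq double-strand-break mapping data
    for topoisomerase II (TOP2) poison experiments. Converts aligned read-end
    BED files to binned coverage, detects break sites by fold enrichment over
    an untreated control, normalizes per-peak signal to cell-percentage using
    zinc-finger-nuclease spike-in cells, computes per-break persistence across
    drug-washout timepoints, decomposes signal into reversible TOP2 cleavage
    complexes, irreversible TOP2 cleavage complexes and protein-free breaks
    from paired exonuclease conditions, and calls maximum DNA end-resection
    endpoints with a sliding-window scan. Includes a seeded synthetic END-seq
    read generator with ground-truth tables for validating every stage by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'io.R'
    'persistence.R'
    'pipeline.R'
    'quantify.R'
    'resection.R'
    'simulate.R'
    'species.R'
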