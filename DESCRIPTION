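Package: teconsex
Title: Cross-Species Conservation of Transposable Element Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the conservation of transposable element
    (TE) expression across related species and the contribution of TEs to
    long non-coding RNAs (lncRNAs). Parses RepeatMasker-style repeat
    tables, joins nested repeat fragments into insertions, lifts intervals
    between genome assemblies through UCSC chain alignments with a
    minimum-remap-ratio rule, quantifies expression with RPKM thresholds,
    tests per-family enrichment of conserved expression with the
    hypergeometric distribution, builds filtered lncRNA catalogs and
    annotates them with TE overlaps. Includes a synthetic multi-species
    dataset generator with planted ground truth so the whole pipeline can
    be exercised end to end without external genome data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
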