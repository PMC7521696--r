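Package: polyhet
Title: Expression Dominance and Heterosis Analysis for Polyploid Hybrid
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative transcriptome analysis of diploid and autotetraploid
    F1 hybrids against their parents: negative-binomial differential expression
    with fold-change and false-discovery-rate gating, replicate quality control
    by within-group correlation, DEG set algebra (parent-parent, hybrid-parent,
    ploidy-specific sets), classification of hybrid-parent DEGs into twelve
    additive and non-additive expression patterns with extraction of heterosis
    candidate genes, mid-parent and high-parent heterosis indices on trait
    tables, cytological proportion statistics, gene-to-QTL interval mapping,
    and hypergeometric over-representation analysis. Includes a
    negative-binomial count simulator with planted dominance patterns for
    method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
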