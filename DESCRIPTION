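Package: cnc4c
Title: 4C Interaction Calling and Conserved Non-Coding Element Proximity
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of circular chromosome conformation capture (4C)
    libraries from filtered alignment tags to interaction calls. Performs
    in-silico DpnII digestion of a reference genome, filters and assigns
    sequence tags to restriction fragments, calls bait-interacting regions
    by a tag-count threshold with bait-flanking exclusion, summarises cis
    versus trans contacts and replicate reproducibility, tests proximity of
    interacting fragments to non-exonic conservation blocks against a
    sampled genomic null with the two-sample Wilcoxon rank-sum test, builds
    bait-bait proximity networks and gene-proximity sets with hypergeometric
    overlap statistics, and ships a fully deterministic synthetic-data
    generator so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
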