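Package: epioverlap
Title: Overlap and Colocalization Analysis of Transgenerational Sperm
    Epimutations
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integration analysis of multi-generation sperm epimutation
    catalogs: differential DNA methylation regions, non-coding RNA loci and
    differential histone retention sites across the F1-F3 generations of
    exposure lineages. Implements dual-threshold extended overlap matrices,
    10 kb-window overlap via symmetric flank extension, Venn partitioning of
    genomic overlap regions, chromosomal colocalization scans, permutation
    tests of overlap against uniformly placed random sites, gene
    association, and a synthetic-catalog generator with planted
    colocalization and retention structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    IRanges,
    S4Vectors,
    optparse
Config/testthat/edition: 3
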