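Package: chromintegrate
Title: Integrated ChIP-Seq Peak and Expression Analysis of Stimulus-Response
    Promoter Architecture
Version: 0.1.0
Authors@R:
    person("THP1", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for the integrated analysis of two-condition ChIP-seq peak
    tracks (histone H3 acetylation, initiating S5P RNA polymerase II, Sp1) and
    replicated expression profiles, as used to study the macrophage early
    inflammatory response to lipopolysaccharide. Provides condition-wise peak
    comparison (common/unique partition and island-widening direction calls),
    genomic-feature and CpG-island annotation of peaks, matrix-similarity
    scanning for TATA boxes in core promoters, fold-change/t-test differential
    expression calls, and the gene-by-gene integration that classifies
    regulated genes into two promoter-architecture groups (TATA-driven,
    H3Ac-free, CpG-poor promoters versus H3Ac-marked, CpG-rich, TATA-less
    promoters). Includes a synthetic-data generator that plants all of these
    structures with known ground truth, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
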