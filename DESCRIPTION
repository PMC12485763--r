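Package: epimosaic
Title: Allele-Specific Methylation Blocks and Epimutation Hotspots in
    Clonal Cell Populations
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing intermediately methylated regions (IMRs)
    as epimutation hotspots in clonal cell populations. Implements
    recurrence-based DMR hotspot discovery from per-CpG methylation count
    tracks, read-level methylation heterogeneity metrics and SNP-partitioned
    allele-specific methylation (ASM) testing, methylation linkage
    disequilibrium (mLD r-squared) and methylation-haplotype-block
    discovery from per-read calls, haplotype-resolved block-level ASM and
    epimutation calling with confounder filters (imprinted regions,
    structural-variant proximity, SNP-dense windows, sex chromosomes),
    clone-switching and timepoint-stability summaries, and tissue-specific
    IMR definition with per-region-class epimutation rates. Ships a
    seedable synthetic-data generator emulating clonal and polyclonal cell
    populations with planted ground truth, so every caller is testable
    end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
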