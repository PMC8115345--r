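Package: scnome
Title: Single-Cell Bisulfite and NOMe-Seq Methylome/Accessibility Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of single-cell bisulfite (scBS-seq) and
    single-cell chromatin-overall-omic (scCOOL-seq / NOMe-seq) cytosine call
    tables: WCG/GCH context classification, per-site and tile-based
    methylation and accessibility estimation, library quality control,
    nucleosome-depleted-region (NDR) detection by sliding-window chi-square
    against the whole-genome background, differential methylation and
    differential openness between cell groups, hypergeometric annotation
    enrichment, promoter CpG-density classification with three-omics
    correlation, and cell-to-cell epigenetic variance with chi-squared
    confidence lower bounds. Ships a calibrated synthetic-cohort generator
    with planted ground truth so every stage is testable without sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    jsonlite,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
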