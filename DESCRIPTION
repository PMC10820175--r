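Package: promhex
Title: Promoter Hexamer Enrichment Analysis with Resampling Nulls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies over-represented hexamer (6-mer) cis-regulatory
    motifs in the 1-kb promoters of focal gene sets, such as genes
    up-regulated by a transcription factor under stress. Promoters are
    extracted TSS-anchored and strand-aware from a genome plus annotation;
    all 4096 hexamers are counted with overlapping windows; expected
    frequencies come from a resampling null (repeated random subsets of a
    background promoter universe) and enrichment is reported as per-hexamer
    Z-scores standardized per 100 promoters. Includes cross-condition
    contrast comparison, annotation of hexamers against a bundled dictionary
    of known plant cis-elements (DRE, ABRE, ARR1AT, MYBST1, ...),
    IUPAC-aware occurrence scanning of promoter sets, and a seeded synthetic
    promoter generator with planted motifs for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    BiocGenerics,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
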