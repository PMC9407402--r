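Package: panheat
Title: Pan-Genome Presence/Absence and Heat-Tolerance Candidate Gene
    Discovery in Rice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for discovering heat-tolerance candidate
    genes from a rice pan-genome. Implements coverage-based gene
    presence/absence (PAV) calling with core/variable classification and
    pan/core growth-curve modelling, Jaccard and SNP-based neighbour-joining
    trees, minor-allele-frequency and missingness SNP filtering, a
    functional-consequence annotator over GFF3 gene models (splice, coding,
    UTR, flanking categories with HIGH/MODERATE/LOW/MODIFIER impact classes),
    selection of SNP alleles specific to highly heat-tolerant accessions,
    cross-dataset differential-expression consensus with contradiction
    exclusion, and marker-delimited QTL interval mapping of the surviving
    candidates. A synthetic-data generator emits a complete toy study
    (FASTA, GFF3, VCF, coverage tracks, DEG tables, QTL markers, metadata)
    with planted ground truth so every stage is verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    minpack.lm,
    purrr,
    methods,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
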