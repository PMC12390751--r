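Package: oxoasym
Title: Strand Asymmetry Analysis of Oxidative Damage Artefacts in Exome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and quantifies strand-asymmetric 8-oxo-guanine (8-oxo-G)
    sequencing artefacts in targeted capture data. Counts high-confidence
    singleton alignment mismatches from pileup text, stratifies them by the
    coding strand annotated in the capture-kit BED and by read alignment
    direction, and computes mismatch-versus-complement asymmetry ratios by
    reference strand, by transcription strand, and by alignment direction,
    with per-flowcell batch summaries. Analyses variant-call asymmetry from
    VCF (filter-status stratification, unique-site cohort aggregation, exact
    binomial departure from composition-derived expectations, trinucleotide
    contexts, F1R2 orientation fractions, and a quality-ordered rebalancing
    filter), estimates the somatic fraction of mismatches, and validates the
    whole pipeline against a mechanistic generative model of single-stranded
    probe capture with pre- and post-capture guanine oxidation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
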