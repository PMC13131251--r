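Package: sleepmeta
Title: Gene-Wise Random-Effects Meta-Analysis of Sleep-Deprivation
    Transcriptome Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Harmonizes per-contrast differential-expression results from
    multiple transcriptional profiling studies of acute sleep deprivation
    in the rodent cortex into a gene-by-contrast effect-size matrix, fits
    per-gene random-effects meta-analysis models (REML tau-squared,
    inverse-variance pooling, Wald inference) with optional moderator
    meta-regression on sleep-deprivation duration and recovery sleep,
    applies Benjamini-Hochberg FDR control, performs preranked gene-set
    enrichment with gene-permutation p-values, and validates pooled
    effects against an independently analysed two-group RNA-Seq count
    matrix (filter, TMM, voom, empirical-Bayes moderation) via direction
    and significance congruence statistics. Includes a synthetic
    multi-study data generator with known ground truth for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    edgeR,
    limma,
    jsonlite
Suggests:
    metafor,
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
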