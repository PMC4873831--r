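Package: polyshock
Title: Transcriptome Shock Analysis for Synthetic Allopolyploids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies gene expression responses to allopolyploidy from
    replicated log2 expression matrices: parental divergence (PEC/PED),
    additivity against the mid-parent value, expression-level dominance
    (ELD) and transgressive expression (TRE), transgenerational
    consistency of nonadditive patterns, and homeolog expression
    partitioning (stable/erasure/novel bias) with subgenome dominance
    summaries from allele-fraction data. Includes an empirical-Bayes
    moderated t-test with Benjamini-Yekutieli FDR control and a
    synthetic-data generator with planted ground truth for every
    classification the pipeline makes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite
Config/testthat/edition: 3
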