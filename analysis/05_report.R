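#!/usr/bin/env Rscript
# Stage 5: reconcile the classification output against the generator's
# planted truth and write a one-table recovery report.

library(polyshock)

calls <- read_calls("results/category_calls.tsv")
pcalls <- read_calls("results/partitioning_calls.tsv")
truth <- structure(
  list(genes = utils::read.delim("results/sim/truth_genes.tsv",
                                 colClasses = "character"),
       patterns = utils::read.delim("results/sim/truth_patterns.tsv",
                                    colClasses = "character")),
  class = "ground_truth")
truth_homeolog <- utils::read.delim("results/sim/truth_homeolog.tsv",
                                    colClasses = "character")

rows <- list()
for (tt in unique(calls$tissue)) {
  tc <- calls[calls$tissue == tt, ]
  sc <- score_pattern_recovery(tc, truth)
  tg <- score_transgen_recovery(find_consistent(tc), truth)
  sp <- score_partitioning_recovery(pcalls[pcalls$tissue == tt, ],
                                    truth_homeolog)
  rows[[tt]] <- data.frame(
    tissue = tt,
    n_calls = sc$n,
    pattern_recovery = round(sc$recovery, 4),
    transgen_sensitivity = round(tg$sensitivity, 4),
    transgen_precision = round(tg$precision, 4),
    partitioning_recovery = round(sp$recovery, 4))
  message(tt, ": pattern recovery ", round(100 * sc$recovery, 1),
          "%, transgenerational sensitivity ",
          round(100 * tg$sensitivity, 1), "%, partitioning recovery ",
          round(100 * sp$recovery, 1), "%")
}
report <- do.call(rbind, rows)
utils::write.table(report, "results/recovery_report.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("wrote results/recovery_report.tsv")
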