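#!/usr/bin/env Rscript
# Stage 4: homeolog partitioning. Calls altered partitioning per
# comparable data point (gene x generation with a category call and
# replicated fractions in polyploid and mix), classifies the qualitative
# outcome, tabulates altered shares within the additive and nonadditive
# expression classes, and summarizes subgenome dominance per genotype.

library(polyshock)

homeolog <- read_homeolog("results/sim/homeolog.tsv")
manifest <- utils::read.delim("results/sim/manifest.tsv",
                              colClasses = "character")
calls <- read_calls("results/category_calls.tsv")
tissues <- unique(calls$tissue)

pcalls <- do.call(rbind, lapply(tissues, function(tt)
  call_partitioning(homeolog, manifest, calls, tt, alpha = 0.05)))
write_calls(pcalls, "results/partitioning_calls.tsv")

for (cls in c("additive", "nonadditive")) {
  tab <- tabulate_comparable(pcalls, cls)
  for (i in seq_len(nrow(tab$by_tissue))) {
    b <- tab$by_tissue[i, ]
    message(cls, " points, ", b$tissue, ": ", b$n_altered, "/", b$n_total,
            " altered (", round(100 * b$proportion, 1), "%)")
  }
  if (!is.null(tab$tissue_comparison)) {
    message(cls, ": between-tissue prop-test p = ",
            signif(tab$tissue_comparison$p_value, 3))
  }
}

dom <- do.call(rbind, lapply(tissues, function(tt) {
  d <- summarize_dominance(homeolog, manifest, tissue = tt)
  d$tissue <- tt
  d
}))
utils::write.table(dom, "results/dominance_summary.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
leaf_nat <- dom[dom$tissue == tissues[1] & dom$role == "natural", ]
if (nrow(leaf_nat)) {
  message("natural accessions, ", tissues[1], ": mean A-fraction ",
          paste(round(leaf_nat$mean_a_fraction, 3), collapse = ", "),
          " vs mix ",
          round(dom$mean_a_fraction[dom$tissue == tissues[1] &
                                    dom$genotype == "mix"], 3))
}
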