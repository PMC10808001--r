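#!/usr/bin/env Rscript
# Localization-stratified statistics over element properties: does the
# basic-residue fraction and hydrophobicity differ between groups while the
# hydrophobic moment stays invariant? Kruskal-Wallis omnibus plus pairwise
# rank-sum tests with common-language effect sizes and Holm adjustment.
#
# Run analysis/02_detect_score.R first.

suppressMessages(library(helix311))

el <- utils::read.delim("results/elements_labelled.tsv")
rep_ <- compare_by_localization(el, c("basic_fraction", "H", "muH"))

for (p in names(rep_)) {
  om <- rep_[[p]]$omnibus
  message(sprintf("%-15s omnibus H = %6.2f, p = %.3g", p, om$statistic,
                  om$p_value))
}

dir.create("results", showWarnings = FALSE)
writeLines(jsonlite::toJSON(rep_, dataframe = "rows", auto_unbox = TRUE,
                            digits = 6),
           "results/localization_stats.json")
pw <- do.call(rbind, lapply(names(rep_), function(p) {
  cbind(property = p, rep_[[p]]$pairwise)
}))
utils::write.table(pw, "results/localization_pairwise.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("pairwise table written to results/localization_pairwise.tsv")
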