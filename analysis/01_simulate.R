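#!/usr/bin/env Rscript
# Generate the synthetic study inputs: a localization-labelled homolog
# family with planted amphipathic 3-11 repeats, decoy backgrounds, and
# instrument traces with planted parameters. Everything is seeded; ground
# truth is written beside the data under results/synthetic/.

suppressMessages(library(helix311))

out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

fam <- synth_family(family_spec(seed = 1))
write_family(fam, file.path(out, "family"))
message(sprintf("family: %d sequences across %d groups",
                length(fam$records), length(unique(vapply(fam$records, `[[`, "", "label")))))

decoys <- synth_decoys(50, c(120, 180), "disordered", seed = 2)
write_fasta(decoys, file.path(out, "decoys.fasta"))

for (kind in c("isotherm", "decay", "thermogram", "anisotropy")) {
  tr <- synth_traces(kind, seed = 3)
  utils::write.table(tr$data, file.path(out, paste0(kind, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
message("instrument traces written with recorded truth parameters")
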