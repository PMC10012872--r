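#!/usr/bin/env Rscript
# Stage 1: generate the synthetic two-age study (sequences with planted
# miRNA sites, NB count matrices, qPCR Ct table, GO map, ground truth).
# Usage: Rscript analysis/01_simulate.R [seed]

suppressMessages(library(ceRNAfly))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
out <- "results/analysis"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = seed)
sim <- simulate_sequences(cfg)
cm <- simulate_counts(sim$truth, cfg)
ct <- simulate_ct(sim$truth, cfg)
gomap <- simulate_go_map(sim$truth, cfg)

for (cls in c("mirna", "mrna", "lncrna", "circrna")) {
  write_fasta(sim$sequences[[cls]], file.path(out, paste0(cls, ".fa")))
  write_tsv(data.frame(feature = rownames(cm[[cls]]), cm[[cls]],
                       check.names = FALSE),
            file.path(out, paste0("counts_", cls, ".tsv")))
}
write_tsv(cm$design, file.path(out, "design.tsv"))
write_tsv(ct, file.path(out, "ct.tsv"))
write_tsv(gomap, file.path(out, "go_map.tsv"))
jsonlite::write_json(sim$truth[c("planted_triples", "planted_sites")],
                     file.path(out, "ground_truth.json"),
                     dataframe = "rows", digits = NA)

cat(sprintf(
  "Simulated %d mRNAs, %d lncRNAs, %d circRNAs, %d miRNAs (seed %d).\n",
  cfg$n_mrna, cfg$n_lncrna, cfg$n_circrna, cfg$n_mirna, seed))
cat(sprintf(
  "Planted %d ceRNA triples (%d binding sites) with |log2FC| = %.1f.\n",
  nrow(sim$truth$planted_triples), nrow(sim$truth$planted_sites),
  cfg$log2fc_effect))
cat(sprintf("Design: %d RNA-seq and %d miRNA-seq libraries across day7/day42.\n",
            sum(cm$design$assay == "rnaseq"),
            sum(cm$design$assay == "mirnaseq")))
cat("Wrote", out, "\n")
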