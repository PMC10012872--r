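#!/usr/bin/env Rscript
# Stage 2: negative-binomial differential expression (day 42 vs day 7) per
# assay, with the per-assay screening profiles.
# Usage: Rscript analysis/02_differential_expression.R

suppressMessages(library(ceRNAfly))
out <- "results/analysis"
design <- read_tsv(file.path(out, "design.tsv"))

read_counts <- function(cls) {
  tab <- read_tsv(file.path(out, paste0("counts_", cls, ".tsv")))
  m <- as.matrix(tab[, -1]); rownames(m) <- tab$feature
  m
}

for (cls in c("mrna", "lncrna", "circrna", "mirna")) {
  de <- de_analysis(read_counts(cls), design, de_profile(cls))
  write_tsv(de, file.path(out, paste0("de_", cls, ".tsv")))
  prof <- de_profile(cls)
  cat(sprintf(
    "%-8s %3d features tested, %2d DE (%d up, %d down) at fold >= %.1f, raw p < %.2f\n",
    cls, nrow(de), sum(de$direction != "ns"), sum(de$direction == "up"),
    sum(de$direction == "down"), prof$fc_cutoff, prof$p_cutoff))
}
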