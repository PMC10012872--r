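#!/usr/bin/env Rscript
# Stage 3: miRanda-style binding-site prediction of DE miRNAs on DE
# sponges (circRNA with wrap-around, lncRNA) and DE mRNA 3'UTRs.
# Usage: Rscript analysis/03_binding_sites.R

suppressMessages(library(ceRNAfly))
out <- "results/analysis"

de_feats <- function(cls) {
  de <- read_tsv(file.path(out, paste0("de_", cls, ".tsv")))
  de$feature[de$direction != "ns"]
}
mir <- read_fasta(file.path(out, "mirna.fa"))
mir <- mir[intersect(names(mir), de_feats("mirna"))]

scan <- function(cls, label) {
  tg <- read_fasta(file.path(out, paste0(cls, ".fa")))
  tg <- tg[intersect(names(tg), de_feats(cls))]
  if (length(tg) == 0 || length(mir) == 0)
    return(suppressWarnings(predict_targets(character(0), character(0), label)))
  predict_targets(mir, tg, label)
}
sites <- rbind(scan("circrna", "circRNA"), scan("lncrna", "lncRNA"),
               scan("mrna", "mRNA_3UTR"))
write_tsv(sites, file.path(out, "sites.tsv"))

cat(sprintf("Scanned %d DE miRNAs; %d sites pass score >= 140, dG <= -10 kcal/mol.\n",
            length(mir), nrow(sites)))
for (cl in unique(sites$target_class))
  cat(sprintf("  %-10s %3d sites on %d targets (all %s)\n", cl,
              sum(sites$target_class == cl),
              length(unique(sites$target[sites$target_class == cl])),
              paste(unique(sites$seed_class[sites$target_class == cl]),
                    collapse = "/")))
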