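#!/usr/bin/env Rscript
# Stage 5: hypergeometric GO enrichment of the network's target mRNAs,
# reporting the 30 terms with the lowest p-values.
# Usage: Rscript analysis/05_enrichment.R

suppressMessages(library(ceRNAfly))
out <- "results/analysis"

triples <- read_tsv(file.path(out, "triples_unfiltered.tsv"))
gomap <- read_tsv(file.path(out, "go_map.tsv"))
query <- unique(triples$mrna)

if (length(query) == 0) {
  cat("No network target mRNAs; nothing to enrich.\n")
  quit(status = 0)
}
res <- hypergeom_enrich(query, gomap)
top <- top_terms(res, n_top = 30)
write_tsv(top, file.path(out, "enrichment.tsv"))

cat(sprintf("Enrichment over %d network mRNAs against %d background genes:\n",
            length(query), res$N[1]))
cat(sprintf("%d terms tested; top term %s (%s) k=%d/K=%d, p = %.3g (BH %.3g)\n",
            nrow(res), top$go_id[1], top$term[1], top$k[1], top$K[1],
            top$p_raw[1], top$p_adj[1]))
for (ns in unique(top$namespace))
  cat(sprintf("  %s: %d of the top %d terms\n", ns,
              sum(top$namespace == ns), nrow(top)))
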