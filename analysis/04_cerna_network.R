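#!/usr/bin/env Rscript
# Stage 4: ceRNA triple construction by shared-miRNA site overlap, the
# sign-consistency mechanism filter, and bipartite network export.
# Usage: Rscript analysis/04_cerna_network.R

suppressMessages(library(ceRNAfly))
out <- "results/analysis"

sites <- read_tsv(file.path(out, "sites.tsv"))
de_tables <- lapply(stats::setNames(nm = c("mrna", "lncrna", "circrna", "mirna")),
                    function(cls) read_tsv(file.path(out, paste0("de_", cls, ".tsv"))))

triples <- find_triples(sites, de_tables)
write_tsv(triples, file.path(out, "triples_unfiltered.tsv"))
kept <- mechanism_filter(triples)
write_tsv(kept, file.path(out, "triples.tsv"))
net <- export_network(kept)
write_tsv(net$edges, file.path(out, "network_edges.tsv"))
write_tsv(net$nodes, file.path(out, "network_nodes.tsv"))

cat(sprintf("%d candidate triples from shared miRNA binding sites.\n",
            nrow(triples)))
cat(sprintf("%d conform to the ceRNA mechanism (sponge/mRNA same trend, miRNA opposite).\n",
            nrow(kept)))
cat(sprintf("Network: %d nodes (%d sponges, %d miRNAs, %d mRNAs), %d edges.\n",
            nrow(net$nodes),
            sum(net$nodes$class %in% c("circRNA", "lncRNA")),
            sum(net$nodes$class == "miRNA"), sum(net$nodes$class == "mRNA"),
            nrow(net$edges)))

# compare against the planted ground truth when available
gt_path <- file.path(out, "ground_truth.json")
if (file.exists(gt_path)) {
  gt <- jsonlite::read_json(gt_path, simplifyVector = TRUE)$planted_triples
  if (length(gt) > 0 && nrow(kept) > 0) {
    key <- function(t) paste(t$sponge, t$mirna, t$mrna)
    tp <- length(intersect(key(kept), key(gt)))
    cat(sprintf("Planted-triple recovery: precision %.2f, recall %.2f.\n",
                tp / nrow(kept), tp / nrow(gt)))
  }
}
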