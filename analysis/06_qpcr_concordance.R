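#!/usr/bin/env Rscript
# Stage 6: qPCR relative quantification (2^-ddCt vs rp49, day-7
# calibrator), Welch t-tests, and direction concordance with RNA-seq.
# Usage: Rscript analysis/06_qpcr_concordance.R

suppressMessages(library(ceRNAfly))
out <- "results/analysis"

ct <- read_tsv(file.path(out, "ct.tsv"))
rq <- delta_delta_ct(ct, reference_gene = "rp49", calibrator = "day7")
write_tsv(rq, file.path(out, "rq.tsv"))

qp <- group_test(rq)
qp <- qp[qp$gene != "rp49", ]
de_all <- do.call(rbind, lapply(c("mrna", "lncrna", "circrna", "mirna"),
                                function(cls) read_tsv(file.path(out, paste0("de_", cls, ".tsv")))))
qp <- concordance(qp, de_all)
write_tsv(qp, file.path(out, "qpcr_concordance.tsv"))

cat(sprintf("qPCR on %d genes (3 replicates per age, rp49 reference):\n",
            nrow(qp)))
cat(sprintf("  %d significant at p < 0.05 (%d at p < 0.01)\n",
            sum(qp$p < 0.05), sum(qp$stars == "**")))
cat(sprintf("  %d of %d concordant (+) with the RNA-seq direction calls\n",
            sum(qp$concordant, na.rm = TRUE), sum(!is.na(qp$concordant))))
print(utils::head(qp[, c("gene", "mean_log2_rq", "p", "stars",
                         "de_direction", "concordant")], 8))
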