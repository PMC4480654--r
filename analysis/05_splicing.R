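#!/usr/bin/env Rscript
# Stage 5: transcript-number-normalised alternative-splicing index.
#
# Computes the per-gene index (mean AS events over 100 random samples of 10
# mapped ESTs) and correlates it with the evolutionary-rate estimates.

library(exonedge)

ds <- read_dataset("results/data")
set.seed(20260929)

spl <- splicing_index_table(ds$est_chains)
cat(sprintf("%d genes with >= 10 mapped ESTs (of %d with any EST)\n",
            sum(!spl$excluded), nrow(spl)))
cat(sprintf("median index among included genes: %.3f\n",
            median(spl$index[!spl$excluded])))

pw <- pairwise_dnds_table(ds$genes, c("ingroup1", "ingroup2"))
m <- merge(spl[!spl$excluded, ], data.frame(gene_id = pw$gene_id,
                                            omega = pw$omega,
                                            valid = pw$valid),
           by = "gene_id")
m <- m[m$valid & !is.na(m$omega), ]
if (nrow(m) >= 10 && length(unique(m$index)) > 1) {
  sp <- spearman(m$index, m$omega)
  cat(sprintf("rho(splicing index, omega) = %.3f (n=%d, p=%.3g)\n",
              sp$rho, sp$n, sp$p))
} else {
  cat("too few genes (or a degenerate index) for a correlation\n")
}
write.table(format(spl, digits = 4), "results/splicing_index.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("per-gene indices written to results/splicing_index.tsv\n")
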