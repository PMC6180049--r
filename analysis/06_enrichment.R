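#!/usr/bin/env Rscript
# Over-representation analysis of the final robust signature against the
# gene-set collection (planted sets + decoys), with permutation FDR.

library(rgsig)

SEED <- 2026
final_up <- readLines("results/final_signature_up.txt")
final_down <- readLines("results/final_signature_down.txt")
universe <- read.delim("results/deg_table.tsv")$gene
gs <- read_gmt("results/fixtures/gene_sets.gmt")

res_up <- permutation_fdr(final_up, gs, universe, n_perm = 1000,
                          seed = SEED + 10, fdr_threshold = 0.05)
res_down <- permutation_fdr(final_down, gs, universe, n_perm = 1000,
                            seed = SEED + 11, fdr_threshold = 0.05)
res_up$signature <- "up"
res_down$signature <- "down"
res <- rbind(res_up, res_down)
write.table(res, "results/enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("tested %d sets against %d up and %d down signature genes\n",
            length(gs), length(final_up), length(final_down)))
cat(sprintf("sets at FDR < 0.05: %d (up), %d (down)\n",
            sum(res_up$significant), sum(res_down$significant)))
cat("\ntop enriched sets (up signature):\n")
print(head(res_up[, c("set", "overlap_count", "expected_count",
                      "p_hyper", "fdr")], 5),
      row.names = FALSE, digits = 3)
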