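#!/usr/bin/env Rscript
# The core of the pipeline: stability of top-k differential gene lists
# under stratified subsampling, the robust gene set, and its intersection
# with the full-cohort signature.

library(rgsig)

SEED <- 2026
x <- read_expression("results/fixtures/expression.tsv",
                     "results/fixtures/phenotype.tsv")

rr <- run_robustness(x, B = 50, n_per_group = 100, k = 50, seed = SEED,
                     verbose = TRUE)
print(rr)

write.table(data.frame(gene = names(rr$selection_count),
                       selection_count = rr$selection_count,
                       selection_fraction = rr$selection_count / rr$B),
            "results/selection_counts.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(overlap = rr$overlap_values),
            "results/overlap_values.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

robust <- robust_set(rr, min_fraction = 0.9)
writeLines(robust, "results/robust_genes.txt")

sig <- structure(list(up = readLines("results/signature_up.txt"),
                      down = readLines("results/signature_down.txt")),
                 class = "gene_signature")
final <- final_signature(robust, sig)
writeLines(final$up, "results/final_signature_up.txt")
writeLines(final$down, "results/final_signature_down.txt")

cat(sprintf("median pairwise overlap: %.3f (k = %d, B = %d)\n",
            rr$median_overlap, rr$k, rr$B))
cat(sprintf("robust set: %d genes selected in >= 90%% of subsamples\n",
            length(robust)))
cat(sprintf("final robust signature: %d of the %d signature genes\n",
            length(signature_genes(final)), length(signature_genes(sig))))
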