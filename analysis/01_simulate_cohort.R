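#!/usr/bin/env Rscript
# Build the synthetic study cohort every later step consumes: a combined
# multi-study case/control expression matrix with 200 planted up- and 200
# planted down-regulated genes, written in the pipeline's exchange formats.

library(rgsig)

dir.create("results/fixtures", recursive = TRUE, showWarnings = FALSE)
SEED <- 2026

sim <- simulate_expression(n_genes = 2000, n_case = 200, n_control = 200,
                           n_up = 200, n_down = 200, effect_mean = 1.5,
                           seed = SEED)
print(sim$matrix)
print(sim$truth)

write_expression(sim$matrix,
                 "results/fixtures/expression.tsv",
                 "results/fixtures/phenotype.tsv")
writeLines(sim$truth$de_genes_up, "results/fixtures/planted_up.txt")
writeLines(sim$truth$de_genes_down, "results/fixtures/planted_down.txt")

# gene-set collection: the planted sets plus 50 random decoys
gs <- simulate_gene_sets(sim$truth, n_decoy_sets = 50, set_size = 50,
                         seed = SEED + 1)
write_gmt(gs, "results/fixtures/gene_sets.gmt")

cat(sprintf("wrote %d-gene x %d-sample cohort (%d planted DE genes) and %d gene sets\n",
            nrow(sim$matrix$values), ncol(sim$matrix$values),
            length(sim$truth$effect_sizes), length(gs)))
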