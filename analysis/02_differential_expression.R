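#!/usr/bin/env Rscript
# Directional differential expression on the full cohort and selection of
# the top-fraction/FDR signature (the analogue of a "top 1% at FDR 0.001"
# gene list on a real combined cohort).

library(rgsig)

x <- read_expression("results/fixtures/expression.tsv",
                     "results/fixtures/phenotype.tsv")
deg <- deg_table(x)
write.table(deg, "results/deg_table.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

sig <- select_signature(deg, top_fraction = 0.01, fdr_threshold = 0.001)
writeLines(sig$up, "results/signature_up.txt")
writeLines(sig$down, "results/signature_down.txt")

planted_up <- readLines("results/fixtures/planted_up.txt")
planted_down <- readLines("results/fixtures/planted_down.txt")
found <- signature_genes(sig)
cat(sprintf("signature: %d up + %d down of %d genes (cap %d per direction)\n",
            length(sig$up), length(sig$down), nrow(deg),
            ceiling(0.005 * nrow(deg))))
cat(sprintf("precision against planted truth: %.3f\n",
            mean(found %in% c(planted_up, planted_down))))

# the most extreme genes by fold change, in the style of a top-DEG table
top <- deg[match(found, deg$gene), c("gene", "t", "p_up", "p_down",
                                     "fold_change")]
top <- top[order(-abs(log2(top$fold_change))), ]
cat("\nmost fold-changed signature genes:\n")
print(head(top, 10), row.names = FALSE, digits = 3)
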