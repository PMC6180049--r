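#!/usr/bin/env Rscript
# Unsupervised hierarchical clustering of all samples on the final robust
# signature: Manhattan distances, Ward linkage, a two-way cut, and Newick
# export of the dendrogram for external tree viewers.

library(rgsig)

x <- read_expression("results/fixtures/expression.tsv",
                     "results/fixtures/phenotype.tsv")
final <- c(readLines("results/final_signature_up.txt"),
           readLines("results/final_signature_down.txt"))

hc <- ward_linkage(manhattan_distances(x, final))
write_newick(hc, "results/dendrogram.nwk")

clusters <- cut_k(hc, n_clusters = 2)
write.table(data.frame(sample_id = names(clusters), cluster = clusters,
                       group = as.character(x$group)),
            "results/cluster_assignments.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# signature-restricted matrix in dendrogram order, for heatmap rendering
ordered <- x$values[final, hc$order, drop = FALSE]
write.table(data.frame(gene = rownames(ordered), ordered,
                       check.names = FALSE),
            "results/ordered_signature_matrix.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

agreement <- label_agreement(clusters, x$group)
cat(sprintf("clustered %d samples on %d signature genes\n",
            length(clusters), length(final)))
cat(sprintf("two-cluster agreement with case/control labels: %.3f\n",
            agreement))
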