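#!/usr/bin/env Rscript
# Stage 2: disease-dysregulated gene sets.
#
# Differential expression (Welch on normalized log2 counts, BH 0.01 /
# |log2FC| > 1), hypergeometric over-representation of the DEGs in each
# gene set (BH 0.01, sizes 6-499), random-walk proximity of the enriched
# sets to the disease targets (restart 0.5, 1000 permutations, BH 0.01),
# and overlap-coefficient redundancy pruning (> 0.5).

suppressMessages(library(synergene))

inp <- "results/synthetic"
out <- "results"
seed <- 101

counts <- read_table(file.path(inp, "counts.tsv"), "counts")
groups <- utils::read.delim(file.path(inp, "groups.tsv"))$group
gene_sets <- read_gmt(file.path(inp, "gene_sets.gmt"))
edges <- read_table(file.path(inp, "edges.tsv"), "edges")
network <- igraph::graph_from_data_frame(edges, directed = FALSE)
targets <- readLines(file.path(inp, "targets.txt"))
truth <- read_truth(file.path(inp, "truth.json"))

de <- call_degs(counts, groups, alpha = 0.01, lfc_cut = 1.0)
utils::write.table(de$table, file.path(out, "de_table.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

enr <- ora(de$degs, de$table$gene, gene_sets)
utils::write.table(enr$table, file.path(out, "ora_table.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

prox <- proximity_permutation_test(network, gene_sets[enr$selected],
                                   targets, n_perm = 1000, seed = seed)
utils::write.table(prox$table, file.path(out, "proximity_table.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

padj <- stats::setNames(enr$table$padj, enr$table$set_id)[prox$selected]
retained <- prune_redundant(gene_sets[prox$selected], padj)
writeLines(retained, file.path(out, "retained_sets.txt"))

planted <- truth$planted_module_ids
cat(sprintf(
  "%d/%d genes called DE; %d sets enriched, %d target-proximal, %d after pruning\nplanted modules recovered: %d/%d (%s)\n",
  length(de$degs), nrow(de$table), length(enr$selected),
  length(prox$selected), length(retained),
  sum(planted %in% retained), length(planted),
  paste(intersect(retained, planted), collapse = ", ")
))
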