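#!/usr/bin/env Rscript
# Stage 3: signature gene sets.
#
# Scores every reference compound on every retained gene set with the
# betweenness-weighted AC1 reversal index (wAC), then keeps the sets whose
# reversal is specific to the disease drugs (one-sided Wilcoxon, p < 0.01)
# and anti-correlated with ln(IC50) drug sensitivity (Pearson r < 0,
# p < 0.01, in at least one panel).

suppressMessages(library(synergene))

inp <- "results/synthetic"
out <- "results"

de_table <- read_table(file.path(out, "de_table.tsv"), "de_table")
gene_sets <- read_gmt(file.path(inp, "gene_sets.gmt"))
retained <- readLines(file.path(out, "retained_sets.txt"))
edges <- read_table(file.path(inp, "edges.tsv"), "edges")
network <- igraph::graph_from_data_frame(edges, directed = FALSE)
ref_profiles <- read_table(file.path(inp, "ref_profiles.tsv"), "profiles")
positives <- readLines(file.path(inp, "positives.txt"))
panels <- list(
  panel1 = read_table(file.path(inp, "sensitivity_panel1.tsv"), "sensitivity"),
  panel2 = read_table(file.path(inp, "sensitivity_panel2.tsv"), "sensitivity")
)

btw <- node_betweenness(network)
wac_ref <- wac_matrix(ref_profiles, de_table, gene_sets[retained], btw,
                      alpha = 0.01, lfc_cut = 0.5)
utils::write.table(wac_ref, file.path(out, "wac_reference.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

wm <- wac_to_matrix(wac_ref)
wil <- compare_groups(wm, positives)
corr <- sensitivity_correlation(wm, panels)
sig <- select_signature(wil, corr, alpha = 0.01, panel_rule = "any")
utils::write.table(sig$verdicts, file.path(out, "signature_verdicts.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(corr, file.path(out, "sensitivity_correlations.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(sig$selected, file.path(out, "signature_sets.txt"))

cat(sprintf(
  "wAC computed for %d compounds x %d sets; %d signature set(s): %s\npositive-drug wAC range on signatures: %.2f..%.2f; negatives median %.2f\n",
  nrow(wm), ncol(wm), length(sig$selected),
  paste(sig$selected, collapse = ", "),
  min(wm[positives, sig$selected]), max(wm[positives, sig$selected]),
  stats::median(wm[setdiff(rownames(wm), positives), sig$selected])
))
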