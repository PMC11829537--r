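#!/usr/bin/env Rscript
# Stage 4: graded regulation scores and candidate pair ranking.
#
# The 50th/80th quantiles of the positive drugs' wAC per signature set
# define weak/moderate/strong grades (0 / 0.5 / 1) for the candidate
# compounds.  PS sums a compound's grades; TCS sums the per-set capped
# pair grades; pairs with PS > 0 members and TCS strictly above
# (n_sets - 1) are the combination candidates.

suppressMessages(library(synergene))

inp <- "results/synthetic"
out <- "results"

de_table <- read_table(file.path(out, "de_table.tsv"), "de_table")
gene_sets <- read_gmt(file.path(inp, "gene_sets.gmt"))
signature <- readLines(file.path(out, "signature_sets.txt"))
edges <- read_table(file.path(inp, "edges.tsv"), "edges")
network <- igraph::graph_from_data_frame(edges, directed = FALSE)
positives <- readLines(file.path(inp, "positives.txt"))
wac_ref <- utils::read.delim(file.path(out, "wac_reference.tsv"))
cand_profiles <- read_table(file.path(inp, "cand_profiles.tsv"), "profiles")

wm_ref <- wac_to_matrix(wac_ref)[, signature, drop = FALSE]
qs <- reference_quantiles(wm_ref, positives)
utils::write.table(qs, file.path(out, "reference_quantiles.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

btw <- node_betweenness(network)
wac_cand <- wac_matrix(cand_profiles, de_table, gene_sets[signature], btw)
gm <- grade_matrix(wac_to_matrix(wac_cand), qs)
utils::write.table(
  data.frame(compound = rownames(gm), gm, ps = rowSums(gm),
             check.names = FALSE),
  file.path(out, "grade_matrix.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE
)

pairs <- rank_candidates(gm)
utils::write.table(pairs, file.path(out, "candidate_pairs.csv"),
                   sep = ",", quote = FALSE, row.names = FALSE)

cat(sprintf(
  "grading quantiles per signature set:\n%s\n%d/%d candidates with PS > 0; %d pairs evaluated, %d above TCS > %d\n",
  paste(sprintf("  %s: q50 = %.2f, q80 = %.2f", qs$set_id, qs$q50, qs$q80),
        collapse = "\n"),
  attr(pairs, "n_eligible"), nrow(gm), attr(pairs, "n_evaluated"),
  nrow(pairs), ncol(gm) - 1
))
if (nrow(pairs)) {
  cat(sprintf("top pair: %s + %s (TCS %.1f)\n",
              pairs$compound_a[1], pairs$compound_b[1], pairs$tcs[1]))
}
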