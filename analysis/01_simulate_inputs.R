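#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study with planted ground truth.
#
# Emits every input the discovery workflow consumes -- expression counts,
# gene sets (GMT), interactome edge list, disease targets, reference and
# candidate perturbation panels, drug-sensitivity panels, the fingerprint
# synergy screen -- plus the truth JSON that later stages are judged
# against.

suppressMessages(library(synergene))

seed <- 101
out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

study <- simulate_study(seed)

write_gene_matrix(study$expression$counts, file.path(out, "counts.tsv"))
utils::write.table(
  data.frame(sample = colnames(study$expression$counts),
             group = study$expression$groups),
  file.path(out, "groups.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
)
write_gmt(study$gene_sets, file.path(out, "gene_sets.gmt"))
utils::write.table(
  setNames(as.data.frame(igraph::as_edgelist(study$network)), c("from", "to")),
  file.path(out, "edges.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
)
writeLines(study$targets, file.path(out, "targets.txt"))
write_gene_matrix(study$ref_panel$profiles, file.path(out, "ref_profiles.tsv"))
writeLines(study$ref_panel$positives, file.path(out, "positives.txt"))
for (pn in names(study$sensitivity)) {
  utils::write.table(study$sensitivity[[pn]],
                     file.path(out, paste0("sensitivity_", pn, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
write_gene_matrix(study$cand_panel$profiles, file.path(out, "cand_profiles.tsv"))

# fingerprint synergy screen (independent of the transcriptomic side)
syn <- generate_synergy_dataset(30, 48, 8, interaction_effect = 1,
                                noise_sd = 0.05, seed = seed + 10L)
utils::write.table(syn$records, file.path(out, "synergy.csv"),
                   sep = ",", quote = FALSE, row.names = FALSE)
utils::write.table(
  data.frame(compound_id = rownames(syn$fingerprints), syn$fingerprints,
             check.names = FALSE),
  file.path(out, "drug_fingerprints.csv"),
  sep = ",", quote = FALSE, row.names = FALSE
)

# synthetic candidate fingerprints: the planted pair carries every causal bit
set.seed(seed + 11L)
ids <- colnames(study$cand_panel$profiles)
cand_fp <- matrix(stats::rbinom(length(ids) * ncol(syn$fingerprints), 1L, 0.3),
                  nrow = length(ids),
                  dimnames = list(ids, colnames(syn$fingerprints)))
cand_fp[study$truth$planted_pair, syn$truth$causal_bits] <- 1L
utils::write.table(
  data.frame(compound_id = rownames(cand_fp), cand_fp, check.names = FALSE),
  file.path(out, "cand_fingerprints.csv"),
  sep = ",", quote = FALSE, row.names = FALSE
)

write_truth(c(study$truth, list(synergy_causal_bits = syn$truth$causal_bits)),
            file.path(out, "truth.json"))

cat(sprintf(
  "simulated study: %d genes, %d gene sets (%d planted), %d reference compounds (%d positives),\n%d candidates with planted pair %s; %d synergy records over %d drugs\n",
  nrow(study$expression$counts), length(study$gene_sets),
  length(study$truth$planted_module_ids),
  ncol(study$ref_panel$profiles), length(study$ref_panel$positives),
  ncol(study$cand_panel$profiles),
  paste(study$truth$planted_pair, collapse = "+"),
  nrow(syn$records), nrow(syn$fingerprints)
))
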