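#!/usr/bin/env Rscript
# Stage 5: structure-based synergy regression and final ranking.
#
# ZIP synergy scores from the screen are IQR-filtered and min-max
# normalized; pairs are featurized as both fingerprint concatenation
# orders and split 80:20 at the unordered-pair level.  Four regressor
# families (randomized trees, bagged trees, gradient boosting, neural
# network) compete under group-aware 5-fold CV; the lowest-CV-RMSE model
# is evaluated on the held-out pairs, its permutation importance is
# reported, and the TCS-passing candidate pairs are re-ranked by its
# order-symmetric predictions.

suppressMessages(library(synergene))

inp <- "results/synthetic"
out <- "results"
seed <- 101

records <- read_table(file.path(inp, "synergy.csv"), "synergy")
fp_tab <- utils::read.csv(file.path(inp, "drug_fingerprints.csv"),
                          check.names = FALSE)
fps <- as.matrix(fp_tab[, -1]); rownames(fps) <- fp_tab$compound_id

prep <- preprocess(records$zip)
rec <- records[prep$keep, ]
feats <- pair_features(rec, fps, prep$values)
sp <- group_split(feats$pair_ids, test_fraction = 0.2, seed = seed)
tr <- feats$pair_ids %in% sp$train

fit <- train_select(feats$X[tr, ], feats$y[tr], feats$pair_ids[tr],
                    folds = 5, seed = seed)
metrics <- do.call(rbind, lapply(names(fit$bundles), function(alg) {
  ev <- evaluate(fit$bundles[[alg]], feats$X[!tr, ], feats$y[!tr])
  data.frame(algorithm = alg, cv_rmse = fit$bundles[[alg]]$cv_rmse,
             test_rmse = ev$rmse, test_r2 = ev$r2, test_mae = ev$mae,
             test_medae = ev$medae)
}))
utils::write.table(metrics, file.path(out, "ml_metrics.csv"),
                   sep = ",", quote = FALSE, row.names = FALSE)

best <- fit$bundles[[fit$best]]
imp <- permutation_importance(best, feats$X[!tr, ], feats$y[!tr],
                              n_repeats = 5, seed = seed)
utils::write.table(imp, file.path(out, "ml_importance.csv"),
                   sep = ",", quote = FALSE, row.names = FALSE)

cat(sprintf("model selection (CV RMSE / test RMSE / test R2):\n%s\nselected: %s\n",
            paste(sprintf("  %-12s %.3f / %.3f / %.2f", metrics$algorithm,
                          metrics$cv_rmse, metrics$test_rmse, metrics$test_r2),
                  collapse = "\n"),
            fit$best))

# re-rank the TCS-passing candidate pairs by predicted synergy
pairs <- utils::read.csv(file.path(out, "candidate_pairs.csv"))
cand_tab <- utils::read.csv(file.path(inp, "cand_fingerprints.csv"),
                            check.names = FALSE)
cand_fp <- as.matrix(cand_tab[, -1]); rownames(cand_fp) <- cand_tab$compound_id
if (nrow(pairs)) {
  bundles <- list(syn48 = best)
  pairs$predicted_synergy <- vapply(seq_len(nrow(pairs)), function(i) {
    fa <- list(syn48 = as_fingerprint(cand_fp[pairs$compound_a[i], ],
                                      pairs$compound_a[i], "syn48"))
    fb <- list(syn48 = as_fingerprint(cand_fp[pairs$compound_b[i], ],
                                      pairs$compound_b[i], "syn48"))
    predict_pair(fa, fb, bundles)$ensemble
  }, numeric(1))
  pairs <- pairs[order(-pairs$predicted_synergy), ]
}
utils::write.table(pairs, file.path(out, "final_ranking.csv"),
                   sep = ",", quote = FALSE, row.names = FALSE)
if (nrow(pairs)) {
  cat(sprintf("final candidate: %s + %s (TCS %.1f, predicted synergy %.3f)\n",
              pairs$compound_a[1], pairs$compound_b[1], pairs$tcs[1],
              pairs$predicted_synergy[1]))
}
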