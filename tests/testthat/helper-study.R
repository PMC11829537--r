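# Shared builders for the end-to-end planted-study tests.

study_config <- function(study, ml_bundles = NULL, cand_fingerprints = NULL,
                         n_perm = 1000) {
  pipeline_config(
    counts = study$expression$counts, groups = study$expression$groups,
    gene_sets = study$gene_sets, network = study$network,
    targets = study$targets,
    ref_profiles = study$ref_panel$profiles,
    positives = study$ref_panel$positives,
    sensitivity = study$sensitivity,
    cand_profiles = study$cand_panel$profiles,
    cand_fingerprints = cand_fingerprints, ml_bundles = ml_bundles,
    n_perm = n_perm, seed = study$truth$seed
  )
}

# fingerprint synergy models are trained once on the fixed synthetic
# screen and reused across transcriptomic replicates (they are
# independent of the transcriptomic side of the study)
.ml_fixture_env <- new.env(parent = emptyenv())
get_ml_fixture <- function() {
  if (!exists("fx", envir = .ml_fixture_env)) {
    syn <- generate_synergy_dataset(30, 48, 8, interaction_effect = 1,
                                    noise_sd = 0.05, seed = 2024)
    prep <- preprocess(syn$records$zip)
    rec <- syn$records[prep$keep, ]
    feats <- pair_features(rec, syn$fingerprints, prep$values)
    fit <- train_select(feats$X, feats$y, feats$pair_ids,
                        algorithms = c("extratrees", "xgboost"),
                        folds = 5, seed = 2024)
    assign("fx", list(bundle = fit$bundles[[fit$best]], syn = syn),
           envir = .ml_fixture_env)
  }
  get("fx", envir = .ml_fixture_env)
}

# synthetic fingerprints for the candidate panel; the planted pair carries
# every causal bit, so a working synergy model scores it highest
cand_fingerprints_for <- function(study, syn, seed) {
  set.seed(seed)
  ids <- colnames(study$cand_panel$profiles)
  fp <- matrix(stats::rbinom(length(ids) * ncol(syn$fingerprints), 1L, 0.3),
               nrow = length(ids),
               dimnames = list(ids, colnames(syn$fingerprints)))
  fp[study$truth$planted_pair, syn$truth$causal_bits] <- 1L
  fp
}
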