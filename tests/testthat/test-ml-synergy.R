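test_that("IQR outlier filtering and min-max normalization follow the rules", {
  res <- preprocess(c(rep(c(1, 2, 3, 4), 5), 100))
  expect_false(res$keep[21])               # fence at Q3 + 1.5 IQR
  expect_true(all(res$keep[1:20]))
  expect_equal(range(res$values), c(0, 1))

  # uniform data already inside the fences loses nothing
  set.seed(2)
  u <- stats::runif(200)
  res_u <- preprocess(u)
  expect_true(all(res_u$keep))
  expect_equal(min(res_u$values), 0)
  expect_equal(max(res_u$values), 1)

  expect_error(preprocess(rep(1, 30)), "constant")
  expect_error(preprocess(c(1, 2)), "at least 20")
})

test_that("grouped splitting keeps order variants of a pair together", {
  ids <- pair_id(sprintf("D%02d", 1:10), sprintf("D%02d", c(2:10, 1)))
  sp <- group_split(ids, test_fraction = 0.2, seed = 1)
  expect_length(sp$test, 2)
  expect_length(sp$train, 8)
  expect_length(intersect(sp$train, sp$test), 0)

  # duplicated rows (both orders) land on one side
  rows <- c(ids, ids)
  side <- ifelse(rows %in% sp$test, "test", "train")
  expect_true(all(tapply(side, rows, function(s) length(unique(s))) == 1))

  sp2 <- group_split(ids, test_fraction = 0.2, seed = 2)
  expect_length(sp2$test, 2)
  expect_false(identical(sort(sp$test), sort(sp2$test)))
})

test_that("evaluation metrics behave analytically", {
  y <- c(0.1, 0.4, 0.2, 0.8, 0.6)
  X <- matrix(0, 5, 2)
  perfect <- list(algorithm = "oracle", models = list(function(X) y))
  res <- evaluate(perfect, X, y)
  expect_equal(res$rmse, 0)
  expect_equal(res$r2, 1)
  expect_equal(res$mae, 0)
  expect_equal(res$medae, 0)

  # a mean predictor has R^2 = 0 by definition, and rmse >= mae (Jensen)
  mean_model <- list(algorithm = "mean",
                     models = list(function(X) rep(mean(y), nrow(X))))
  res_mean <- evaluate(mean_model, X, y)
  expect_equal(res_mean$r2, 0)
  expect_gte(res_mean$rmse, res_mean$mae)

  expect_error(evaluate(perfect, X[0, , drop = FALSE], numeric(0)),
               "empty test")
})

test_that("training selects a signal-capturing model and respects groups", {
  syn <- generate_synergy_dataset(25, 32, 6, 1, 0.05, seed = 3)
  prep <- preprocess(syn$records$zip)
  rec <- syn$records[prep$keep, ]
  feats <- pair_features(rec, syn$fingerprints, prep$values)
  sp <- group_split(feats$pair_ids, 0.2, seed = 4)
  tr <- feats$pair_ids %in% sp$train
  fit <- train_select(feats$X[tr, ], feats$y[tr], feats$pair_ids[tr],
                      algorithms = c("extratrees", "xgboost"),
                      folds = 5, seed = 5)
  expect_named(fit$bundles, c("extratrees", "xgboost"))
  expect_true(fit$best %in% names(fit$bundles))
  for (b in fit$bundles) {
    expect_length(b$models, 5)
    expect_gte(b$cv_rmse, 0)
  }
  # no pair spans CV folds: the fold map is defined per unique pair
  fold_rows <- fit$bundles[[1]]$fold_of_pair[feats$pair_ids[tr]]
  expect_true(all(tapply(fold_rows, feats$pair_ids[tr],
                         function(f) length(unique(f))) == 1))

  # the selected model beats the mean-predictor baseline on held-out pairs
  te <- !tr
  ev <- evaluate(fit$bundles[[fit$best]], feats$X[te, ], feats$y[te])
  baseline_rmse <- sqrt(mean((mean(feats$y[tr]) - feats$y[te])^2))
  expect_lt(ev$rmse, baseline_rmse)
  expect_gte(ev$rmse, ev$mae)

  # determinism for the deterministic families
  fit2 <- train_select(feats$X[tr, ], feats$y[tr], feats$pair_ids[tr],
                       algorithms = c("extratrees", "xgboost"),
                       folds = 5, seed = 5)
  expect_equal(fit$bundles$extratrees$cv_rmse, fit2$bundles$extratrees$cv_rmse)
  expect_equal(predict_bundle(fit$bundles$extratrees, feats$X[te, ]),
               predict_bundle(fit2$bundles$extratrees, feats$X[te, ]))
})

test_that("pair prediction is invariant to argument order", {
  syn <- generate_synergy_dataset(20, 24, 4, 1, 0.05, seed = 7)
  prep <- preprocess(syn$records$zip)
  rec <- syn$records[prep$keep, ]
  feats <- pair_features(rec, syn$fingerprints, prep$values)
  fit <- train_select(feats$X, feats$y, feats$pair_ids,
                      algorithms = "xgboost", folds = 5, seed = 8)
  bundles <- list(syn32 = fit$bundles$xgboost)
  fa <- list(syn32 = as_fingerprint(syn$fingerprints["D001", ], "D001", "syn32"))
  fb <- list(syn32 = as_fingerprint(syn$fingerprints["D002", ], "D002", "syn32"))
  p_ab <- predict_pair(fa, fb, bundles)
  p_ba <- predict_pair(fb, fa, bundles)
  expect_equal(p_ab$ensemble, p_ba$ensemble, tolerance = 1e-12)

  # identical fingerprints give identical order predictions
  p_aa <- predict_pair(fa, fa, bundles)
  expect_equal(unname(p_aa$per_fp), p_aa$ensemble)

  # ensemble over several constant per-fp predictions is their mean
  expect_equal(mean(c(0.2, 0.4, 0.6)), 0.4)
})

test_that("permutation importance highlights causal bits and zeroes constants", {
  syn <- generate_synergy_dataset(25, 24, 4, 1.5, 0.03, seed = 9)
  prep <- preprocess(syn$records$zip)
  rec <- syn$records[prep$keep, ]
  fp <- syn$fingerprints
  fp[, 24] <- 0L  # force a constant column
  feats <- pair_features(rec, fp, prep$values)
  fit <- train_select(feats$X, feats$y, feats$pair_ids,
                      algorithms = "xgboost", folds = 5, seed = 10)
  imp <- permutation_importance(fit$bundles$xgboost, feats$X, feats$y,
                                n_repeats = 3, seed = 11)
  causal_feats <- c(sprintf("a_bit%03d", syn$truth$causal_bits),
                    sprintf("b_bit%03d", syn$truth$causal_bits))
  top_decile <- imp$feature[seq_len(ceiling(nrow(imp) / 10))]
  expect_gte(length(intersect(top_decile, causal_feats)), 3)
  expect_equal(imp$importance[imp$feature == "a_bit024"], 0, tolerance = 1e-12)

  imp2 <- permutation_importance(fit$bundles$xgboost, feats$X, feats$y,
                                 n_repeats = 3, seed = 11)
  expect_identical(imp, imp2)
})
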