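#' Outlier filtering and min-max normalization of synergy targets
#'
#' Records outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` (type-7 quartiles) are
#' discarded; the survivors are min-max mapped to `[0, 1]`.  With zero IQR
#' but non-constant data the fence filter is skipped with a warning;
#' constant targets are an error.  The fences and scaling parameters are
#' returned so that predictions can be mapped back to the original scale.
#'
#' @param values Numeric vector of synergy scores (`>= 20` values).
#' @return List with `values` (normalized survivors), `keep` (logical
#'   index into the input), `fences`, `range` (pre-scaling min/max).
#' @export
preprocess <- function(values) {
  if (length(values) < 20L) stop("need at least 20 records")
  if (stats::sd(values) == 0) stop("constant synergy targets")
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  if (iqr == 0) {
    warning("zero interquartile range; outlier filter skipped")
    keep <- rep(TRUE, length(values))
  } else {
    fences <- c(q[1] - 1.5 * iqr, q[2] + 1.5 * iqr)
    keep <- values >= fences[1] & values <= fences[2]
  }
  kept <- values[keep]
  rng <- range(kept)
  if (diff(rng) == 0) stop("constant synergy targets after filtering")
  list(values = (kept - rng[1]) / diff(rng), keep = keep,
       fences = if (iqr > 0) c(q[1] - 1.5 * iqr, q[2] + 1.5 * iqr) else NULL,
       range = rng)
}

#' Grouped train/test split at the unordered-pair level
#'
#' Pairs (not rows) are partitioned, so both concatenation-order variants
#' of a combination always land on the same side of the split.
#'
#' @param pair_ids Character vector of order-free pair ids (one per row;
#'   repeated ids allowed).
#' @param test_fraction Fraction of pairs assigned to the test set
#'   (default 0.2).
#' @param seed Integer seed.
#' @return List with `train` and `test` (character vectors of pair ids).
#' @export
group_split <- function(pair_ids, test_fraction = 0.2, seed = 1) {
  u <- unique(pair_ids)
  if (length(u) < 10L) stop("need at least 10 pairs")
  set.seed(seed)
  n_test <- round(test_fraction * length(u))
  test <- sample(u, n_test)
  list(train = setdiff(u, test), test = test)
}

.fit_model <- function(algorithm, X, y, seed) {
  set.seed(seed)
  switch(algorithm,
    extratrees = ranger::ranger(
      x = X, y = y, num.trees = 300, splitrule = "extratrees",
      num.random.splits = 1, seed = seed, num.threads = 1
    ),
    bagged_trees = ranger::ranger(
      x = X, y = y, num.trees = 200, mtry = ncol(X), seed = seed,
      num.threads = 1
    ),
    random_forest = ranger::ranger(
      x = X, y = y, num.trees = 300, seed = seed, num.threads = 1
    ),
    xgboost = xgboost::xgboost(
      x = as.matrix(X), y = y, nrounds = 150, learning_rate = 0.1,
      max_depth = 6, subsample = 0.8, verbosity = 0, nthreads = 1,
      seed = seed
    ),
    nnet = nnet::nnet(
      x = as.matrix(X), y = y, size = 8, linout = TRUE, decay = 0.01,
      maxit = 200, MaxNWts = 100000, trace = FALSE
    ),
    stop(sprintf("unknown algorithm '%s'", algorithm))
  )
}

.predict_model <- function(fit, X) {
  if (is.function(fit)) {
    fit(X)
  } else if (inherits(fit, "ranger")) {
    stats::predict(fit, data = X, num.threads = 1)$predictions
  } else if (inherits(fit, "xgb.Booster")) {
    stats::predict(fit, as.matrix(X))
  } else {
    as.numeric(stats::predict(fit, as.matrix(X)))
  }
}

#' Cross-validated training and model selection
#'
#' Trains each regressor family with group-aware 5-fold cross-validation
#' (folds partition unordered pairs, so no pair spans folds); the
#' cross-validation RMSE is the mean held-out-fold RMSE, and the best
#' algorithm is the argmin.  Each bundle keeps the five fold models for
#' bagged prediction.  Default families: randomized trees
#' (`"extratrees"`), bagged trees, gradient-boosted trees (`"xgboost"`),
#' and a feed-forward network (`"nnet"`).
#'
#' @param X Numeric feature matrix (rows = order variants of pairs).
#' @param y Numeric target (normalized synergy).
#' @param pair_ids Character order-free pair id per row.
#' @param algorithms Character vector of family names.
#' @param folds Number of CV folds (default 5).
#' @param seed Integer seed.
#' @return List with `bundles` (named list; each with `algorithm`,
#'   `models`, `fold_of_pair`, `fold_rmse`, `cv_rmse`) and `best`.
#' @export
train_select <- function(X, y, pair_ids,
                         algorithms = c("extratrees", "bagged_trees",
                                        "xgboost", "nnet"),
                         folds = 5, seed = 1) {
  stopifnot(nrow(X) == length(y), length(pair_ids) == length(y))
  u <- unique(pair_ids)
  set.seed(seed)
  fold_of_pair <- stats::setNames(
    sample(rep_len(seq_len(folds), length(u))), u
  )
  fold_row <- fold_of_pair[pair_ids]
  bundles <- lapply(algorithms, function(alg) {
    models <- vector("list", folds)
    fold_rmse <- rep(NA_real_, folds)
    for (k in seq_len(folds)) {
      tr <- fold_row != k
      if (stats::sd(y[tr]) == 0) {
        warning(sprintf("%s: fold %d skipped (constant training target)", alg, k))
        next
      }
      fit <- .fit_model(alg, X[tr, , drop = FALSE], y[tr], seed + k)
      pred <- .predict_model(fit, X[!tr, , drop = FALSE])
      models[[k]] <- fit
      fold_rmse[k] <- sqrt(mean((pred - y[!tr])^2))
    }
    usable <- which(!is.na(fold_rmse))
    if (length(usable) < 3L) {
      stop(sprintf("%s: fewer than 3 usable folds", alg))
    }
    list(algorithm = alg, models = models[usable],
         fold_of_pair = fold_of_pair, fold_rmse = fold_rmse[usable],
         cv_rmse = mean(fold_rmse[usable]))
  })
  names(bundles) <- algorithms
  cv <- vapply(bundles, `[[`, numeric(1), "cv_rmse")
  list(bundles = bundles, best = names(which.min(cv)))
}

#' Bagged prediction from a trained bundle
#'
#' @param bundle One element of `train_select()$bundles`.
#' @param X Feature matrix.
#' @return Mean of the fold models' predictions.
#' @export
predict_bundle <- function(bundle, X) {
  preds <- vapply(bundle$models, function(m) .predict_model(m, X),
                  numeric(nrow(X)))
  rowMeans(matrix(preds, nrow = nrow(X)))
}

#' Test-set evaluation of a bundle
#'
#' Predictions are the average across the fold models; metrics are
#' computed on the normalized target scale.
#'
#' @param bundle Trained bundle.
#' @param X,y Test features and targets (pairs disjoint from training).
#' @return List with `rmse`, `r2`, `mae`, `medae`.
#' @export
evaluate <- function(bundle, X, y) {
  if (length(y) == 0L) stop("empty test set")
  pred <- predict_bundle(bundle, X)
  res <- pred - y
  list(rmse = sqrt(mean(res^2)),
       r2 = 1 - sum(res^2) / sum((y - mean(y))^2),
       mae = mean(abs(res)),
       medae = stats::median(abs(res)))
}

#' Order-symmetric synergy prediction for one compound pair
#'
#' Per fingerprint type, the pair is featurized in both concatenation
#' orders, each order is scored by the bagged bundle, and the two scores
#' are averaged; the ensemble prediction is the mean across fingerprint
#' types.  The result is invariant to argument order.
#'
#' @param fps_a,fps_b Named lists of `"fingerprint"` objects keyed by
#'   fingerprint type (must cover `names(bundles)`).
#' @param bundles Named list of trained bundles keyed by fingerprint
#'   type.
#' @return List with `per_fp` (named numeric) and `ensemble`.
#' @export
predict_pair <- function(fps_a, fps_b, bundles) {
  per_fp <- vapply(names(bundles), function(ft) {
    if (is.null(fps_a[[ft]]) || is.null(fps_b[[ft]])) {
      stop(sprintf("missing %s fingerprint for one pair member", ft))
    }
    pf <- featurize_pair(fps_a[[ft]], fps_b[[ft]])
    X <- rbind(pf$AB, pf$BA)
    mean(predict_bundle(bundles[[ft]], X))
  }, numeric(1))
  list(per_fp = per_fp, ensemble = mean(per_fp))
}

#' Permutation importance of fingerprint features
#'
#' Each feature column of the test matrix is shuffled `n_repeats` times;
#' the importance is the mean increase in bagged-prediction RMSE over the
#' unshuffled baseline.  Non-informative (e.g. constant) columns score
#' about zero.
#'
#' @param bundle Trained bundle.
#' @param X,y Test features and targets.
#' @param n_repeats Shuffles per feature (default 5).
#' @param seed Integer seed.
#' @return Data frame with columns `feature`, `importance`, sorted
#'   descending.
#' @export
permutation_importance <- function(bundle, X, y, n_repeats = 5, seed = 1) {
  set.seed(seed)
  base_rmse <- sqrt(mean((predict_bundle(bundle, X) - y)^2))
  imp <- vapply(seq_len(ncol(X)), function(j) {
    mean(vapply(seq_len(n_repeats), function(r) {
      Xp <- X
      Xp[, j] <- Xp[sample.int(nrow(X)), j]
      sqrt(mean((predict_bundle(bundle, Xp) - y)^2)) - base_rmse
    }, numeric(1)))
  }, numeric(1))
  nm <- colnames(X)
  if (is.null(nm)) nm <- sprintf("f%04d", seq_len(ncol(X)))
  out <- data.frame(feature = nm, importance = imp, stringsAsFactors = FALSE)
  out[order(-out$importance), ]
}

#' Assemble the order-duplicated feature matrix for a synergy table
#'
#' Convenience builder used by the workflow: every record (unordered
#' pair) becomes two rows, orders AB and BA, with concatenated
#' fingerprints.
#'
#' @param records Data frame with columns drug_a, drug_b.
#' @param fingerprints Drugs x bits 0/1 matrix.
#' @param y Optional numeric target parallel to `records`.
#' @return List with `X`, `pair_ids` (length `2 * nrow(records)`), and
#'   `y` duplicated to match.
#' @export
pair_features <- function(records, fingerprints, y = NULL) {
  a <- fingerprints[records$drug_a, , drop = FALSE]
  b <- fingerprints[records$drug_b, , drop = FALSE]
  X <- rbind(cbind(a, b), cbind(b, a))
  colnames(X) <- c(paste0("a_", colnames(fingerprints)),
                   paste0("b_", colnames(fingerprints)))
  rownames(X) <- NULL
  ids <- pair_id(records$drug_a, records$drug_b)
  list(X = X, pair_ids = c(ids, ids),
       y = if (is.null(y)) NULL else c(y, y))
}
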