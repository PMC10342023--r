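# Grouped cross-validation of the susceptibility scorer, with the
# training-side negative sampling ratio as an experimental knob. All
# fold-level fitting (normalization bounds included) sees training rows
# only; test folds are evaluated on their full, unsampled rows.

#' Cross-validate a susceptibility scorer
#'
#' For each fold: corpus-level normalization bounds and the scorer are
#' fitted on the training rows only (negatives subsampled to `neg_ratio`
#' per positive), then every test row is scored and the fold AUC is
#' computed on the full test rows. Grouping is by structure (default), so
#' peptide bonds of one protein never appear on both sides of a fold;
#' `grouped = FALSE` gives plain row-level folds.
#'
#' @param dataset Labeled dataset from [build_dataset()] with raw
#'   `rel_acc`/`loop_len` columns (normalization happens per fold), built
#'   with `neg_ratio = Inf` so the full negative pool is available.
#' @param k Number of folds (default 10).
#' @param neg_ratio Training negatives per positive (default 1);
#'   `Inf` uses all training negatives.
#' @param seed Integer seed (fold shuffle and negative draws derive from
#'   it).
#' @param features Model feature columns; default from [model_features()].
#' @param source_kind Feature regime.
#' @param grouped Group folds by structure (default TRUE).
#' @param scorer List with `fit(X, y)` and `predict(fit, X)`; default the
#'   package's LDA.
#' @return Object of class `cv_result`: `fold_auc` (numeric k-vector),
#'   `mean_auc`, `median_auc`, and the per-fold test indices.
#' @export
cross_validate <- function(dataset, k = 10, neg_ratio = 1, seed = 1,
                           features = NULL,
                           source_kind = c("experimental", "predicted"),
                           grouped = TRUE, scorer = lda_scorer_interface()) {
  source_kind <- match.arg(source_kind)
  if (is.null(features)) features <- model_features(source_kind)
  if (grouped) {
    folds <- group_kfold(dataset$group, k = k, seed = seed)
  } else {
    set.seed(as.integer(seed))
    idx <- sample(nrow(dataset))
    folds <- split(idx, rep(seq_len(k), length.out = length(idx)))
  }
  fold_auc <- numeric(k)
  for (f in seq_len(k)) {
    test_idx <- folds[[f]]
    train <- dataset[-test_idx, , drop = FALSE]
    test <- dataset[test_idx, , drop = FALSE]
    if (length(unique(train$label)) < 2 ||
        length(unique(test$label)) < 2) {
      fold_auc[f] <- NA_real_
      next
    }
    train_s <- sample_training_ratio(train, neg_ratio,
                                     seed = as.integer(seed) + 1000L + f)
    nrm <- normalize_features(train_s)
    fit <- scorer$fit(as.matrix(nrm$feats[, features, drop = FALSE]),
                      train_s$label)
    test_n <- normalize_features(test, bounds = nrm$bounds)$feats
    sc <- scorer$predict(fit, as.matrix(test_n[, features, drop = FALSE]))
    fold_auc[f] <- roc_auc(sc, test$label)$auc
  }
  structure(
    list(fold_auc = fold_auc,
         mean_auc = mean(fold_auc, na.rm = TRUE),
         median_auc = stats::median(fold_auc, na.rm = TRUE),
         folds = folds, k = k, neg_ratio = neg_ratio, seed = seed,
         features = features, grouped = grouped),
    class = "cv_result"
  )
}

sample_training_ratio <- function(train, neg_ratio, seed) {
  if (!is.finite(neg_ratio)) return(train)
  pos <- which(train$label == 1)
  neg <- which(train$label == 0)
  n_neg <- min(length(neg), round(neg_ratio * length(pos)))
  set.seed(as.integer(seed))
  train[c(pos, sample(neg, n_neg)), , drop = FALSE]
}

#' Default pluggable-scorer interface wrapping the package LDA
#'
#' Scorers are `list(fit = function(X, y), predict = function(fit, X))`;
#' any classifier exposing that pair can be cross-validated.
#'
#' @param ridge Ridge passed to [lda_fit()].
#' @return Scorer interface list.
#' @export
lda_scorer_interface <- function(ridge = 1e-6) {
  list(fit = function(X, y) lda_fit(X, y, ridge = ridge),
       predict = function(fit, X) lda_predict(fit, X))
}

#' Gaussian naive Bayes scorer interface
#'
#' The second classifier shipped with the package (diagonal-covariance
#' Gaussian class-conditionals); usable anywhere the LDA interface is.
#'
#' @return Scorer interface list.
#' @export
gnb_scorer_interface <- function() {
  list(
    fit = function(X, y) gaussian_nb_fit(as.matrix(X), as.integer(y)),
    predict = function(fit, X) gaussian_nb_predict(fit, as.matrix(X))
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV (%s, 1:%s train ratio): mean AUC %.3f, median %.3f\n",
              x$k, if (x$grouped) "grouped" else "row-level",
              format(x$neg_ratio), x$mean_auc, x$median_auc))
  invisible(x)
}

#' Class-ratio sweep for training-side negative sampling
#'
#' Runs [cross_validate()] at several training negative:positive ratios
#' and several seeds, keeping the evaluation side fixed (full test folds),
#' so the ratios are directly comparable.
#'
#' @param dataset Labeled dataset (full negative pool).
#' @param ratios Numeric vector of negatives-per-positive ratios.
#' @param seeds Integer vector of seeds.
#' @param ... Passed to [cross_validate()].
#' @return Data frame with columns `ratio`, `seed`, `mean_auc`,
#'   `median_auc`.
#' @export
ratio_sweep <- function(dataset, ratios = c(1, 2, 5, 10), seeds = 1:3,
                        ...) {
  out <- expand.grid(ratio = ratios, seed = seeds)
  res <- lapply(seq_len(nrow(out)), function(i) {
    cv <- cross_validate(dataset, neg_ratio = out$ratio[i],
                         seed = out$seed[i], ...)
    c(mean_auc = cv$mean_auc, median_auc = cv$median_auc)
  })
  cbind(out, do.call(rbind, res))
}
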