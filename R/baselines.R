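# Per-fold fitting primitives for the classical rankers. Both return a
# ranking_result over the training rows of one fold; select_features()
# aggregates across folds.

lasso_fold_rank <- function(x, y, seed = 1L, nfolds = 5L, lambda = NULL) {
  set.seed(seed)
  co <- if (is.null(lambda)) {
    # penalty strength by nested CV on the training rows
    fit <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                             nfolds = nfolds, standardize = FALSE)
    as.numeric(stats::coef(fit, s = "lambda.min"))[-1]
  } else {
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                          lambda = lambda, standardize = FALSE)
    as.numeric(stats::coef(fit))[-1]
  }
  scores <- stats::setNames(abs(co), colnames(x))
  new_ranking_result("lasso", scores, keep = scores > 0)
}

rf_fold_rank <- function(x, y, seed = 1L, n_trees = 500L, top_k = 10L) {
  set.seed(seed)
  fit <- randomForest::randomForest(x, factor(y), ntree = n_trees)
  imp <- fit$importance[, "MeanDecreaseGini"]
  scores <- stats::setNames(as.numeric(imp), colnames(x))
  keep <- stats::setNames(rank(-scores, ties.method = "first") <= top_k,
                          colnames(x))
  new_ranking_result("rf", scores, keep)
}

#' LASSO feature ranking
#'
#' Fits an L1-penalized logistic model on the training rows of each fold
#' (penalty strength chosen by nested cross-validation on those rows) and
#' ranks features by the absolute value of their coefficients, averaged
#' over folds. Features are z-scored with training-fold statistics before
#' fitting. Features with zero averaged coefficient form the dropped set.
#'
#' @param ft Feature table.
#' @param folds Fold assignment from [make_folds()].
#' @param seed Root seed.
#' @param ... Passed to the per-fold fit (`nfolds` of the nested CV).
#' @return Aggregated `ranking_result` (method `"lasso"`).
#' @export
lasso_rank <- function(ft, folds, seed = 1L, ...) {
  select_features(ft, folds, method = "lasso", seed = seed, ...)
}

#' Random-forest feature ranking
#'
#' Ranks features by mean-decrease-in-impurity (Gini) importance from a
#' random forest fitted on the training rows of each fold, averaged over
#' folds. The forest is a dense method, so the keep mask is simply the
#' top `top_k` features by score.
#'
#' @inheritParams lasso_rank
#' @param ... Passed to the per-fold fit (`n_trees`, default 500;
#'   `top_k`, default 10).
#' @return Aggregated `ranking_result` (method `"rf"`).
#' @export
rf_rank <- function(ft, folds, seed = 1L, ...) {
  select_features(ft, folds, method = "rf", seed = seed, ...)
}
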