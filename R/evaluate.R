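binary_metrics <- function(truth, pred, positive = "diabetic") {
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  tn <- sum(pred != positive & truth != positive)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  c(accuracy = (tp + tn) / length(truth), precision = precision,
    recall = recall, f1 = f1)
}

#' Evaluate a feature subset with a fixed-configuration SVM
#'
#' Scores a feature subset with an RBF-kernel support vector machine under
#' stratified cross-validation. The hyperparameters are held fixed
#' (default `gamma = 0.1`, `C = 1`) so that differences between feature
#' subsets, not classifier tuning, drive the comparison. Features are
#' z-scored per fold with training-fold statistics. Precision, recall and
#' F1 treat `diabetic` as the positive class; F1 is the per-fold harmonic
#' mean, averaged afterwards.
#'
#' @param ft Feature table.
#' @param features Character vector of feature names to use; default all.
#' @param folds Fold assignment from [make_folds()].
#' @param gamma,cost RBF kernel width and soft-margin penalty.
#' @return A `metrics_report`: list with `mean`, `sd` (named vectors over
#'   accuracy/precision/recall/f1) and `per_fold` (matrix).
#' @export
svm_evaluate <- function(ft, folds, features = feature_names(ft),
                         gamma = 0.1, cost = 1) {
  stopifnot(length(features) >= 1)
  missing <- setdiff(features, feature_names(ft))
  if (length(missing) > 0) {
    stop("feature(s) absent from table: ", paste(missing, collapse = ", "))
  }
  x <- feature_matrix(ft)[, features, drop = FALSE]
  y <- feature_labels(ft)
  fold_ids <- sort(unique(folds))
  per_fold <- t(vapply(fold_ids, function(f) {
    tr <- which(folds != f)
    te <- which(folds == f)
    if (length(unique(y[tr])) < 2) stop("single-class training fold")
    xs <- zscore_by_train(x, tr)
    fit <- e1071::svm(xs[tr, , drop = FALSE], y[tr], kernel = "radial",
                      gamma = gamma, cost = cost)
    pred <- stats::predict(fit, xs[te, , drop = FALSE])
    binary_metrics(y[te], pred)
  }, numeric(4)))
  rownames(per_fold) <- paste0("fold", fold_ids)
  structure(list(mean = colMeans(per_fold),
                 sd = apply(per_fold, 2, stats::sd),
                 per_fold = per_fold,
                 gamma = gamma, cost = cost, features = features),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report: %d features, gamma = %g, C = %g>\n",
              length(x$features), x$gamma, x$cost))
  for (m in names(x$mean)) {
    cat(sprintf("  %-9s %.4f +/- %.4f\n", m, x$mean[m], x$sd[m]))
  }
  invisible(x)
}

#' Randomized search over SVM hyperparameters
#'
#' Log-uniform random search over the RBF kernel width `gamma` (default
#' range 1e-4 to 10) and soft-margin penalty `C` (default 1e-2 to 100),
#' scored by mean cross-validated F1 via [svm_evaluate()].
#'
#' @inheritParams svm_evaluate
#' @param n_iter Number of random configurations (>= 1).
#' @param gamma_range,cost_range Search ranges (log-uniform).
#' @param seed Integer seed for the parameter draws.
#' @return List with `gamma`, `cost`, `report` (the best configuration's
#'   `metrics_report`) and `trace` (data.frame of all draws and their F1).
#' @export
svm_optimize <- function(ft, folds, features = feature_names(ft),
                         n_iter = 200L, gamma_range = c(1e-4, 10),
                         cost_range = c(1e-2, 100), seed = 1L) {
  stopifnot(n_iter >= 1)
  set.seed(seed)
  # draw (gamma, cost) pairs sequentially so that a longer search extends a
  # shorter one under the same seed
  u <- matrix(stats::runif(2 * n_iter), ncol = 2, byrow = TRUE)
  gammas <- exp(log(gamma_range[1]) + u[, 1] * diff(log(gamma_range)))
  costs <- exp(log(cost_range[1]) + u[, 2] * diff(log(cost_range)))
  f1 <- numeric(n_iter)
  reports <- vector("list", n_iter)
  for (i in seq_len(n_iter)) {
    reports[[i]] <- svm_evaluate(ft, folds, features, gamma = gammas[i],
                                 cost = costs[i])
    f1[i] <- reports[[i]]$mean[["f1"]]
  }
  best <- which.max(f1)
  list(gamma = gammas[best], cost = costs[best], report = reports[[best]],
       trace = data.frame(gamma = gammas, cost = costs, f1 = f1))
}

# Class remapping from the earlier 7-class NTR scheme over [25, 35) (C1 =
# [28,29), ..., C4 = [31,32)) to the present 10-class scheme over [18, 37):
# equal temperature intervals, so C1->C5, C2->C6, C3->C7, C4->C8.
REFERENCE_NTR_REMAP <- c(NTR_C1 = "NTR_C5", NTR_C2 = "NTR_C6",
                         NTR_C3 = "NTR_C7", NTR_C4 = "NTR_C8")

#' Prior-art reference feature list
#'
#' The ten features previously reported as the most relevant for diabetic
#' foot classification: TCI, NTR_C4, NTR_C3, MPA_mean, LPA_mean, LPA_ET,
#' LCA_mean, highest temperature, NTR_C2 and NTR_C1 — with two
#' adaptations needed to evaluate them against the present schema. First,
#' the earlier NTR classes are remapped onto the classes covering the same
#' temperature intervals here (C4 -> C8, C3 -> C7, C2 -> C6, C1 -> C5).
#' Second, the earlier work did not distinguish feet, so each feature is
#' resolved at lookup time as the mean of its `L_` and `R_` columns
#' ("highest temperature" resolves to the whole-foot maximum).
#'
#' @return Character vector of the ten reference feature names (schema
#'   terms, footless).
#' @export
reference_feature_list <- function() {
  raw <- c("TCI", "NTR_C4", "NTR_C3", "MPA_mean", "LPA_mean", "LPA_ET",
           "LCA_mean", "highest temperature", "NTR_C2", "NTR_C1")
  vapply(raw, function(f) {
    if (f == "highest temperature") return("max")
    if (f %in% names(REFERENCE_NTR_REMAP)) return(REFERENCE_NTR_REMAP[[f]])
    f
  }, character(1), USE.NAMES = FALSE)
}

#' Resolve footless reference features against a feature table
#'
#' Adds one column per reference feature, computed as the mean of the
#' corresponding left- and right-foot columns of the table.
#'
#' @param ft Feature table following [feature_schema()].
#' @param features Footless feature names (default
#'   [reference_feature_list()]).
#' @return Feature table holding `label` (and `source` if present) plus
#'   the resolved reference columns.
#' @export
resolve_reference_features <- function(ft, features = reference_feature_list()) {
  cols <- lapply(features, function(f) {
    lr <- paste(c("L", "R"), f, sep = "_")
    missing <- setdiff(lr, names(ft))
    if (length(missing) > 0) {
      stop("cannot resolve reference feature '", f, "': column(s) ",
           paste(missing, collapse = ", "), " absent from table")
    }
    (ft[[lr[1]]] + ft[[lr[2]]]) / 2
  })
  out <- ft[, intersect(META_COLUMNS, names(ft)), drop = FALSE]
  out[features] <- cols
  out
}
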