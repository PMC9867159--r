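META_COLUMNS <- c("label", "source")

#' Feature-table accessors
#'
#' A feature table is a data.frame with a `label` factor column
#' (`healthy`/`diabetic`), an optional `source` provenance column, and
#' numeric feature columns. `feature_matrix()` returns the numeric matrix,
#' `feature_names()` the feature column names and `feature_labels()` the
#' label factor.
#'
#' @param ft A feature table.
#' @return See description.
#' @export
feature_matrix <- function(ft) {
  as.matrix(ft[, feature_names(ft), drop = FALSE])
}

#' @rdname feature_matrix
#' @export
feature_names <- function(ft) {
  setdiff(names(ft), META_COLUMNS)
}

#' @rdname feature_matrix
#' @export
feature_labels <- function(ft) {
  ft$label
}

#' Fuse feature tables from several cohorts
#'
#' Row-concatenates feature tables that share an identical feature name
#' set, retaining a `source` provenance column. No value transformation is
#' applied during fusion.
#'
#' @param tables Named (or unnamed) list of feature tables.
#' @return Fused feature table with a `source` column.
#' @export
fuse_datasets <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1)
  ref <- feature_names(tables[[1]])
  for (i in seq_along(tables)) {
    nm <- feature_names(tables[[i]])
    if (!identical(sort(nm), sort(ref))) {
      extra <- setdiff(nm, ref)
      missing <- setdiff(ref, nm)
      stop("feature name sets differ between tables: ",
           if (length(extra)) paste("extra:", paste(extra, collapse = ", ")) else "",
           if (length(missing)) paste(" missing:", paste(missing, collapse = ", ")) else "")
    }
  }
  src_names <- names(tables)
  if (is.null(src_names)) src_names <- paste0("table", seq_along(tables))
  out <- do.call(rbind, lapply(seq_along(tables), function(i) {
    tab <- tables[[i]]
    tab <- tab[, c("label", ref)]
    tab$source <- src_names[i]
    tab
  }))
  rownames(out) <- NULL
  out[, c("label", "source", ref)]
}

#' Balance classes with SMOTE
#'
#' Oversamples the minority class up to the majority count using the
#' synthetic minority oversampling technique: each synthetic sample is a
#' convex combination `x + u * (nn - x)`, `u ~ U(0,1)`, of a minority
#' sample `x` and one of its `k_neighbors` nearest minority neighbors
#' (Euclidean distance in feature space). Original rows are preserved
#' verbatim; synthetic rows carry `source = "smote"`.
#'
#' @param ft Feature table with exactly two classes present.
#' @param k_neighbors Number of minority nearest neighbors (default 5).
#' @param seed Integer seed for neighbor and interpolation draws.
#' @return Balanced feature table.
#' @export
smote_balance <- function(ft, k_neighbors = 5L, seed = 1L) {
  y <- feature_labels(ft)
  counts <- table(factor(y))
  counts <- counts[counts > 0]
  if (length(counts) != 2) stop("smote_balance requires exactly two classes present")
  if (max(counts) == min(counts)) return(ft)
  minority <- names(counts)[which.min(counts)]
  n_new <- max(counts) - min(counts)
  min_idx <- which(y == minority)
  if (length(min_idx) <= k_neighbors) {
    stop(sprintf("minority class has %d samples, not more than k_neighbors = %d; use a smaller k",
                 length(min_idx), k_neighbors))
  }
  x <- feature_matrix(ft)
  xm <- x[min_idx, , drop = FALSE]
  d <- as.matrix(stats::dist(xm))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k_neighbors)]))

  set.seed(seed)
  base <- sample.int(nrow(xm), n_new, replace = TRUE)
  pick <- nn[cbind(base, sample.int(k_neighbors, n_new, replace = TRUE))]
  u <- stats::runif(n_new)
  synth <- xm[base, , drop = FALSE] + u * (xm[pick, , drop = FALSE] - xm[base, , drop = FALSE])

  add <- data.frame(label = factor(rep(minority, n_new), levels = levels(y)),
                    synth, check.names = FALSE)
  if ("source" %in% names(ft)) add$source <- "smote"
  out <- rbind(ft, add[, names(ft)])
  rownames(out) <- NULL
  out
}

#' Single-feature AUCROC scores
#'
#' Scores each feature by the area under the ROC curve of a univariate
#' logistic model predicting the class label.
#'
#' @param ft Feature table.
#' @return Named numeric vector of AUCROC values in \[0.5, 1\] (direction
#'   auto-chosen, so a perfectly anti-predictive feature also scores 1).
#' @export
feature_aucroc <- function(ft) {
  y <- feature_labels(ft)
  x <- feature_matrix(ft)
  yb <- as.integer(y == levels(y)[2])
  vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    if (stats::sd(v) == 0) return(NA_real_)
    fit <- suppressWarnings(stats::glm(yb ~ v, family = stats::binomial()))
    as.numeric(suppressMessages(pROC::auc(yb, stats::fitted(fit),
                                          direction = "<", quiet = TRUE)))
  }, numeric(1)) |> stats::setNames(colnames(x))
}

#' Prune highly correlated features
#'
#' Removes redundant features by a deterministic greedy procedure: every
#' feature is scored by its univariate logistic AUCROC; features are
#' visited in descending score (ties broken by name); a feature whose
#' absolute Pearson correlation with an already-kept feature exceeds
#' `r_threshold` is dropped. Constant features (undefined correlation) are
#' dropped with a warning.
#'
#' @param ft Feature table with at least two samples per class.
#' @param r_threshold Absolute Pearson correlation above which a pair is
#'   considered redundant (default 0.95).
#' @return List with `table` (pruned feature table) and `report`
#'   (data.frame of dropped features, their keeper and the correlation).
#' @export
prune_correlated <- function(ft, r_threshold = 0.95) {
  y <- feature_labels(ft)
  if (any(table(y) < 2)) stop("need at least two samples per class")
  x <- feature_matrix(ft)
  report <- data.frame(dropped = character(0), kept = character(0),
                       r = numeric(0), stringsAsFactors = FALSE)

  const <- colnames(x)[apply(x, 2, stats::sd) == 0]
  if (length(const) > 0) {
    warning("dropping constant feature(s): ", paste(const, collapse = ", "))
    report <- rbind(report, data.frame(dropped = const, kept = NA_character_,
                                       r = NA_real_))
    x <- x[, setdiff(colnames(x), const), drop = FALSE]
  }

  scores <- feature_aucroc(ft)[colnames(x)]
  ord <- colnames(x)[order(-scores, colnames(x))]
  cm <- abs(stats::cor(x))
  kept <- character(0)
  for (f in ord) {
    if (length(kept) == 0 || all(cm[f, kept] <= r_threshold)) {
      kept <- c(kept, f)
    } else {
      over <- kept[cm[f, kept] > r_threshold]
      keeper <- over[which.max(cm[f, over])]
      report <- rbind(report, data.frame(dropped = f, kept = keeper,
                                         r = cm[f, keeper]))
    }
  }
  kept <- intersect(feature_names(ft), kept)  # restore input column order
  keep_cols <- c(intersect(META_COLUMNS, names(ft)), kept)
  list(table = ft[, keep_cols], report = report)
}

#' Stratified cross-validation folds
#'
#' Partitions samples into `n_folds` folds, stratified by class so that
#' fold class proportions match the global ones within one sample per
#' class.
#'
#' @param labels Class label factor/vector.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed.
#' @return Integer vector of fold ids (1..n_folds), one per sample.
#' @export
make_folds <- function(labels, n_folds = 5L, seed = 1L) {
  labels <- factor(labels)
  if (min(table(labels)) < n_folds) {
    stop("too few samples in the smallest class for ", n_folds, " folds")
  }
  set.seed(seed)
  fold <- integer(length(labels))
  offset <- 0L
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    idx <- sample(idx)
    # rotate the fold sequence between classes so that remainder samples
    # do not pile into the same folds
    fold[idx] <- ((seq_along(idx) - 1L + offset) %% n_folds) + 1L
    offset <- (offset + length(idx)) %% n_folds
  }
  fold
}

#' Z-score features using training-fold statistics
#'
#' Centers and scales every feature column by the mean and standard
#' deviation computed on the training rows only, and applies the same
#' transform to all rows. Zero-variance columns are left centered but
#' unscaled.
#'
#' @param x Numeric feature matrix.
#' @param train_idx Row indices of the training set.
#' @return Matrix of the same shape, standardized.
#' @export
zscore_by_train <- function(x, train_idx) {
  mu <- colMeans(x[train_idx, , drop = FALSE])
  sdv <- apply(x[train_idx, , drop = FALSE], 2, stats::sd)
  sdv[sdv == 0] <- 1
  sweep(sweep(x, 2, mu), 2, sdv, "/")
}
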