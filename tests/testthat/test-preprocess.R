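fake_table <- function(n, label, seed, features = c("A", "B", "C")) {
  set.seed(seed)
  df <- data.frame(label = factor(rep(label, length.out = n),
                                  levels = c("healthy", "diabetic")),
                   matrix(rnorm(n * length(features)), n, length(features)))
  names(df)[-1] <- features
  df
}

test_that("dataset fusion concatenates matching tables and keeps provenance", {
  inaoe <- rbind(fake_table(122, "diabetic", 1), fake_table(45, "healthy", 2))
  local <- fake_table(22, "healthy", 3)
  fused <- fuse_datasets(list(inaoe = inaoe, local = local))
  expect_equal(nrow(fused), 189)
  expect_equal(sum(fused$source == "local"), 22)

  twice <- fuse_datasets(list(a = local, b = local))
  expect_equal(nrow(twice), 44)
  expect_identical(feature_names(twice), feature_names(local))

  other <- fake_table(5, "healthy", 4, features = c("A", "B", "D"))
  expect_error(fuse_datasets(list(local, other)), "differ")
})

test_that("SMOTE balances to the majority count by convex interpolation", {
  tab <- rbind(fake_table(122, "diabetic", 1), fake_table(67, "healthy", 2))
  bal <- smote_balance(tab, seed = 1)
  expect_equal(nrow(bal), 244)
  expect_equal(as.integer(table(feature_labels(bal))), c(122L, 122L))
  # originals preserved verbatim
  expect_equal(bal[seq_len(189), ], tab, ignore_attr = TRUE)

  balanced <- rbind(fake_table(10, "diabetic", 3), fake_table(10, "healthy", 4))
  expect_identical(smote_balance(balanced, seed = 1), balanced)

  expect_error(smote_balance(rbind(fake_table(10, "diabetic", 5),
                                   fake_table(4, "healthy", 6)), seed = 1),
               "smaller k")

  # each synthetic row lies on a segment between two original minority rows
  small <- rbind(fake_table(10, "diabetic", 7), fake_table(6, "healthy", 8))
  out <- smote_balance(small, seed = 9)
  synth <- feature_matrix(out)[(nrow(small) + 1):nrow(out), , drop = FALSE]
  minors <- feature_matrix(small)[feature_labels(small) == "healthy", , drop = FALSE]
  for (i in seq_len(nrow(synth))) {
    on_segment <- FALSE
    for (a in seq_len(nrow(minors))) {
      for (b in seq_len(nrow(minors))) {
        if (a == b) next
        dir <- minors[b, ] - minors[a, ]
        rel <- synth[i, ] - minors[a, ]
        u <- sum(rel * dir) / sum(dir * dir)
        if (u >= 0 && u <= 1 && sqrt(sum((rel - u * dir)^2)) < 1e-8) {
          on_segment <- TRUE
        }
      }
    }
    expect_true(on_segment)
  }
})

test_that("correlation pruning keeps the stronger feature of redundant pairs", {
  set.seed(1)
  n <- 100
  y <- rep(c("healthy", "diabetic"), each = n / 2)
  a <- rnorm(n) + (y == "diabetic") * 2      # strong predictor
  b <- a + rnorm(n, sd = 0.05)               # near-duplicate of a, weaker
  c_ <- rnorm(n)                             # independent noise
  tab <- data.frame(label = factor(y, levels = c("healthy", "diabetic")),
                    A = a, B = b, C = c_)
  expect_gt(abs(cor(a, b)), 0.95)
  pr <- prune_correlated(tab)
  expect_setequal(feature_names(pr$table), c("A", "C"))
  expect_equal(pr$report$dropped, "B")
  expect_equal(pr$report$kept, "A")

  # exact duplicate column: exactly one survives
  dup <- data.frame(label = tab$label, A = a, A2 = a, C = c_)
  prd <- prune_correlated(dup)
  expect_equal(sum(c("A", "A2") %in% feature_names(prd$table)), 1L)

  # nothing correlated: unchanged
  ind <- fake_table(60, c("healthy", "diabetic"), 2,
                    features = c("X", "Y", "Z"))
  pri <- prune_correlated(ind)
  expect_identical(pri$table, ind)
  expect_equal(nrow(pri$report), 0L)

  # constant feature dropped with a warning
  k <- tab
  k$K <- 1
  expect_warning(prk <- prune_correlated(k), "constant")
  expect_false("K" %in% feature_names(prk$table))
})

test_that("no surviving pair exceeds the correlation threshold", {
  set.seed(3)
  n <- 80
  base <- matrix(rnorm(n * 4), n, 4)
  x <- cbind(base, base[, 1:2] + rnorm(n * 2, sd = 0.02), rnorm(n))
  colnames(x) <- sprintf("V%d", 1:7)
  tab <- data.frame(label = factor(rep(c("healthy", "diabetic"), each = n / 2),
                                   levels = c("healthy", "diabetic")), x)
  pr <- prune_correlated(tab, r_threshold = 0.95)
  surv <- feature_matrix(pr$table)
  cm <- abs(cor(surv))
  diag(cm) <- 0
  expect_lt(max(cm), 0.95)

  # column order invariance (same scores, ties broken by name)
  tab2 <- tab[, c("label", rev(colnames(x)))]
  pr2 <- prune_correlated(tab2, r_threshold = 0.95)
  expect_setequal(feature_names(pr$table), feature_names(pr2$table))
})

test_that("stratified folds have the documented sizes and determinism", {
  y244 <- factor(rep(c("healthy", "diabetic"), each = 122),
                 levels = c("healthy", "diabetic"))
  f <- make_folds(y244, 5, seed = 1)
  sizes <- tabulate(f, 5)
  expect_true(all(sizes %in% c(48L, 49L)))
  expect_true(all((244 - sizes) %in% c(195L, 196L)))
  # stratification: per-fold class counts within one of each other
  for (k in 1:5) {
    counts <- table(y244[f == k])
    expect_lte(abs(diff(as.integer(counts))), 1)
  }

  y10 <- factor(rep(c("healthy", "diabetic"), 5),
                levels = c("healthy", "diabetic"))
  f10 <- make_folds(y10, 5, seed = 2)
  for (k in 1:5) {
    expect_equal(as.integer(table(y10[f10 == k])), c(1L, 1L))
  }

  expect_identical(make_folds(y244, 5, seed = 9), make_folds(y244, 5, seed = 9))
  expect_error(make_folds(y10, 6), "too few")
})

test_that("z-scoring uses training-fold statistics only", {
  set.seed(4)
  x <- matrix(rnorm(60, mean = 5, sd = 3), 20, 3)
  tr <- 1:12
  z <- zscore_by_train(x, tr)
  expect_equal(colMeans(z[tr, ]), rep(0, 3), tolerance = 1e-12)
  expect_equal(apply(z[tr, ], 2, sd), rep(1, 3), tolerance = 1e-12)
  # held-out rows transformed with the same parameters, not their own
  mu <- colMeans(x[tr, ]); sdv <- apply(x[tr, ], 2, sd)
  expect_equal(z[15, ], (x[15, ] - mu) / sdv, tolerance = 1e-12)
})
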