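test_that("summary statistics match direct moment formulas", {
  expect_equal(summary_stats(c(26, 28))[c("mean", "std", "max", "min")],
               c(mean = 27, std = 1, max = 28, min = 26))
  expect_equal(summary_stats(c(30, 30, 30))[c("std", "skew", "kurtosis")],
               c(std = 0, skew = 0, kurtosis = 0))
  set.seed(11)
  v <- round(runif(12, 18, 36), 3)
  expect_equal(summary_stats(v), oracle_moments(v), tolerance = 1e-9)
  expect_error(summary_stats(numeric(0), region = "L_MPA"), "L_MPA")
})

test_that("NTR occupancy equals a per-pixel tally and sums to one", {
  tab <- ntr_class_table()
  occ <- ntr_occupancy(rep(30.5, 7), tab)
  expect_equal(unname(occ[7]), 1)
  expect_equal(sum(occ[-7]), 0)
  occ2 <- ntr_occupancy(c(28.5, 28.5, 29.5, 29.5), tab)
  expect_equal(unname(occ2[c(5, 6)]), c(0.5, 0.5))
  set.seed(7)
  for (i in 1:5) {
    v <- runif(50, 16, 39)  # deliberately spills outside [18, 37)
    occ <- ntr_occupancy(v, tab)
    expect_equal(unname(occ), oracle_ntr_tally(v, tab), tolerance = 1e-9)
    expect_equal(sum(occ), 1, tolerance = 1e-9)
  }
  expect_error(ntr_occupancy(numeric(0), tab), "empty")
})

test_that("estimated temperature is the occupancy-weighted classmark sum", {
  tab <- ntr_class_table()
  one_hot <- function(i) replace(numeric(10), i, 1)
  expect_equal(estimated_temperature(one_hot(7), tab), 30.5)
  expect_equal(estimated_temperature(0.5 * one_hot(5) + 0.5 * one_hot(6), tab), 29)
  mix <- 0.2 * one_hot(1) + 0.3 * one_hot(4) + 0.5 * one_hot(9)
  expect_equal(estimated_temperature(mix, tab),
               0.2 * 20.0 + 0.3 * 27.5 + 0.5 * 32.5)
  expect_error(estimated_temperature(rep(0.2, 10), tab), "sum to 1")
  # ET bounded by occupied classmarks
  set.seed(3)
  for (i in 1:20) {
    occ <- runif(10)
    occ <- occ / sum(occ)
    et <- estimated_temperature(occ, tab)
    marks <- tab$classmark[occ > 0]
    expect_gte(et, min(marks))
    expect_lte(et, max(marks))
  }
})

test_that("ETD is the unsigned symmetric inter-foot difference", {
  expect_equal(etd(30.5, 30.5), 0)
  expect_equal(etd(30, 28), 2)
  set.seed(5)
  for (i in 1:100) {
    a <- runif(1, 18, 37)
    b <- runif(1, 18, 37)
    expect_equal(etd(a, b), etd(b, a))
    expect_gte(etd(a, b), 0)
  }
})

test_that("hot spot estimator honors the occupancy floor", {
  tab <- ntr_class_table()
  one_hot <- function(i) replace(numeric(10), i, 1)
  expect_equal(hot_spot_estimator(one_hot(7), tab), 30.5)
  expect_equal(hot_spot_estimator(0.9 * one_hot(5) + 0.1 * one_hot(10), tab), 35.0)
  expect_equal(hot_spot_estimator(0.97 * one_hot(5) + 0.03 * one_hot(10), tab), 28.5)
  # nothing reaches the floor: hottest occupied class wins
  thin <- c(0.04, 0.04, rep(0, 7), 0.02)
  expect_equal(hot_spot_estimator(thin / sum(thin) * sum(thin), tab,
                                  min_occupancy = 0.5), 35.0)
  expect_error(hot_spot_estimator(numeric(10), tab), "all-zero")
})

test_that("thermal change index is the mean absolute deviation from controls", {
  refs <- reference_temps()
  means <- stats::setNames(refs$mean, refs$angiosome)
  expect_equal(unname(thermal_change_index(means, refs)), rep(0, 5))
  means["MPA"] <- 26.8
  expect_equal(thermal_change_index(means, refs)[["MPA"]], 1.0)
  set.seed(9)
  for (i in 1:10) {
    m <- stats::setNames(runif(4, 20, 35), refs$angiosome)
    tci <- thermal_change_index(m, refs)
    expect_equal(unname(tci["foot"]), mean(abs(m - refs$mean)), tolerance = 1e-9)
  }
  expect_error(thermal_change_index(means[1:3], refs), "LCA")
})

test_that("feature extraction follows the naming schema with a constant count", {
  schema <- feature_schema()
  expect_true(all(c("R_LPA_min", "L_MPA_NTR_C3", "Foot_ETD", "MCA_ETD",
                    "L_kurtosis", "R_MPA_HSE", "L_TCI", "R_NTR_C5",
                    "L_max", "R_std") %in% schema))
  expect_equal(anyDuplicated(schema), 0L)

  s1 <- make_subject("healthy", foot_geometry(40L, 24L), seed = 1)
  s2 <- make_subject("diabetic", foot_geometry(40L, 24L), seed = 2)
  f1 <- extract_features(s1)
  f2 <- extract_features(s2)
  expect_identical(names(f1), schema)
  expect_identical(names(f1), names(f2))
  expect_equal(length(f1), length(schema))
})

test_that("identical feet give zero ETD everywhere", {
  f <- extract_features(make_twin_subject(4))
  etd_features <- grep("_ETD$", names(f), value = TRUE)
  expect_equal(length(etd_features), 5L)
  expect_equal(unname(f[etd_features]), rep(0, 5))
})

test_that("features are invariant to pixel order within a region", {
  s <- make_subject("diabetic", foot_geometry(40L, 24L), seed = 6)
  f0 <- extract_features(s)
  # swap two pixel values inside the same region on the left foot
  idx <- which(s$left$mask == 2L)[c(1, 5)]
  s$left$grid[idx] <- s$left$grid[rev(idx)]
  expect_equal(extract_features(s), f0, tolerance = 1e-12)
})

test_that("an empty region is reported by name", {
  s <- make_subject("healthy", foot_geometry(40L, 24L), seed = 8)
  s$left$mask[s$left$mask == 3L] <- 4L  # erase MCA
  expect_error(extract_features(s), "L_MCA")
})

test_that("subject records round-trip through CSV + JSON", {
  s <- make_subject("diabetic", foot_geometry(20L, 12L), seed = 3, id = "T1")
  d <- tempfile("subj")
  write_subject(s, d)
  r <- read_subject(d, "T1")
  expect_equal(r$label, "diabetic")
  expect_equal(r$left$grid, s$left$grid, tolerance = 1e-12)
  expect_identical(r$right$mask, s$right$mask)
  unlink(d, recursive = TRUE)
})
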