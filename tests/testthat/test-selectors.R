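test_that("binary dropout masks have the stated zero rate and unit mean", {
  set.seed(1)
  expect_equal(binary_dropout_mask(0, 100), rep(1, 100))
  expect_error(binary_dropout_mask(1, 10), "rho")

  m <- binary_dropout_mask(0.2, 1e5)
  expect_true(all(m %in% c(0, 1.25)))
  expect_lt(abs(mean(m == 0) - 0.2), 0.004)   # ~3 binomial SEs
  for (rho in c(0.1, 0.5, 0.8)) {
    mm <- binary_dropout_mask(rho, 1e5)
    se <- sd(mm) / sqrt(1e5)
    expect_lt(abs(mean(mm) - 1), 3 * se)
  }
})

test_that("variational weight samples match the stated posterior", {
  set.seed(2)
  expect_equal(sample_variational_weights(3, 0), 3)
  expect_equal(sample_variational_weights(0, 5), 0)
  expect_error(sample_variational_weights(1, -0.1), "non-negative")

  w <- sample_variational_weights(rep(2, 1e5), 0.25)
  expect_lt(abs(var(w) - 1), 0.03)   # alpha * theta^2 = 1
  expect_lt(abs(mean(w) - 2), 3 * sd(w) / sqrt(1e5))
})

test_that("concrete gates relax Bernoulli dropout", {
  expect_equal(sample_concrete_gate(0.5, 0.3, eps = 0.5), 0.5)
  expect_error(sample_concrete_gate(0.5, 0), "temperature")
  expect_error(sample_concrete_gate(1.2, 0.5), "rho")

  set.seed(3)
  keep <- sample_concrete_gate(rep(0.9, 1e5), t = 0.05)
  expect_lt(abs(mean(keep < 0.5) - 0.9), 0.01)  # low-T limit ~ Bern(0.9) drop

  # keep-gate monotonically decreasing in rho at fixed eps, t
  rhos <- seq(0.05, 0.95, by = 0.05)
  keeps <- sample_concrete_gate(rhos, t = 0.4, eps = rep(0.37, length(rhos)))
  expect_true(all(diff(keeps) < 0))
})

test_that("the SGVB objective scales and weights its terms exactly", {
  ll <- c(-0.3, -1.2)
  expect_equal(sgvb_objective(ll, kl_term = 4, n_total = 10, batch_size = 2,
                              lambda = 0),
               -(10 / 2) * sum(ll))
  l1 <- sgvb_objective(ll, 4, 10, 2, lambda = 1)
  l05 <- sgvb_objective(ll, 4, 10, 2, lambda = 0.5)
  expect_equal(l1 - l05, 0.5 * 4)
  expect_equal(sgvb_objective(ll, 4, 10, 2, 1), -(10 / 2) * (-1.5) + 4,
               tolerance = 1e-9)
  expect_error(sgvb_objective(c(-1, NaN), 4, 10, 2, 1), "non-finite")
})

test_that("the variational KL approximation has the documented shape", {
  grid <- seq(-8, 8, by = 0.25)
  per_feature <- vapply(grid, variational_kl, numeric(1))
  expect_true(all(diff(per_feature) < 0))      # monotone decreasing in log alpha
  expect_lt(abs(variational_kl(10)), 1e-3)     # vanishes for huge alpha
  la <- c(-1, 0.5, 2)
  expect_equal(variational_kl(c(la, la)), 2 * variational_kl(la))
})

test_that("the concrete penalty counts expected active features", {
  expect_lt(concrete_penalty(rep(1 - 1e-9, 5)), 1e-8)
  expect_gt(concrete_penalty(rep(1e-9, 5)), 1 - 1e-8)
  expect_equal(concrete_penalty(c(0.2, 0.8)), 0.5)
  expect_error(concrete_penalty(c(0.5, 1)), "rho")
})

test_that("the annealing schedule ramps linearly and caps at one", {
  expect_equal(lambda_schedule(0), 0)
  expect_equal(lambda_schedule(200), 0.5)
  expect_equal(lambda_schedule(400), 1)
  expect_equal(lambda_schedule(473), 1)
})

test_that("analytic gate gradients match finite differences", {
  selector_batch <- thermoselect:::selector_batch
  mlp_init <- thermoselect:::mlp_init
  draw_noise <- thermoselect:::draw_noise
  for (kind in c("variational", "concrete")) {
    set.seed(42)
    d <- 7; m <- 6
    x <- matrix(rnorm(m * d), m, d)
    yb <- sample(1:2, m, TRUE)
    cfg <- train_config(kind = kind, hidden = c(5L, 4L))
    gate <- if (kind == "variational") {
      list(theta = rnorm(d, 1, 0.2), log_sigma2 = rnorm(d, -2, 0.5))
    } else {
      list(eta = rnorm(d))
    }
    mlp <- mlp_init(d, cfg$hidden)
    noise <- draw_noise(kind, m, d, cfg$hidden, cfg$hidden_dropout)
    base <- selector_batch(gate, mlp, x, yb, kind, cfg, 0.7, 50, noise)
    h <- 1e-6
    for (pn in names(gate)) {
      for (j in c(1L, 3L, d)) {
        gp <- gate; gp[[pn]][j] <- gp[[pn]][j] + h
        gm <- gate; gm[[pn]][j] <- gm[[pn]][j] - h
        num <- (selector_batch(gp, mlp, x, yb, kind, cfg, 0.7, 50, noise)$loss -
                selector_batch(gm, mlp, x, yb, kind, cfg, 0.7, 50, noise)$loss) / (2 * h)
        ana <- base$gate_grads[[pn]][j]
        expect_lt(abs(num - ana) / max(1e-6, abs(num)), 1e-4)
        expect_true(ana != 0)  # every gate parameter receives gradient
      }
    }
  }
})

test_that("training is deterministic under a fixed seed", {
  tb <- make_tabular(n_per_class = 40, n_features = 10, n_informative = 3,
                     effect_size = 2, seed = 1)
  x <- feature_matrix(tb$table)
  y <- feature_labels(tb$table)
  for (kind in c("variational", "concrete")) {
    cfg <- train_config(kind = kind, epochs = 25L, seed = 5)
    a <- train_selector(x, y, cfg)
    b <- train_selector(x, y, cfg)
    expect_identical(a[names(a) != "log"], b[names(b) != "log"])
    expect_identical(a$log, b$log)
  }
})

test_that("the comparable training objective decreases over 500 epochs", {
  tb <- make_tabular(n_per_class = 100, n_features = 50, n_informative = 10,
                     effect_size = 2, seed = 1)
  x <- feature_matrix(tb$table)
  y <- feature_labels(tb$table)
  smoothed <- function(v, at) mean(v[(at - 4):(at + 5)])
  for (kind in c("variational", "concrete")) {
    st <- train_selector(x, y, train_config(kind = kind, seed = 3))
    expect_lt(smoothed(st$log$objective, 495 - 5),
              smoothed(st$log$objective, 10))
  }
})

test_that("thresholding converts gate parameters into rankings and masks", {
  # variational: alpha = 9 sits exactly at rho_eff = 0.9 and is kept
  st_v <- structure(list(kind = "variational", theta = c(1, 1),
                         log_sigma2 = log(c(9, 10) * (1 + 1e-8)),
                         feature_names = c("a", "b")),
                    class = "selector_state")
  rr_v <- rank_and_sparsify(st_v, tau = 0.9)
  expect_identical(unname(rr_v$keep), c(TRUE, FALSE))
  expect_equal(rr_v$sparse_rate, 0.5)

  st_c <- structure(list(kind = "concrete",
                         eta = stats::qlogis(c(0.95, 0.5, 0.99)),
                         feature_names = c("f1", "f2", "f3")),
                    class = "selector_state")
  rr_c <- rank_and_sparsify(st_c, tau = 0.9)
  expect_identical(unname(rr_c$keep), c(FALSE, TRUE, FALSE))
  expect_equal(rr_c$sparse_rate, 2 / 3)
  # ordering equals an independent sort of 1 - rho_eff
  rho <- c(0.95, 0.5, 0.99)
  expect_identical(rr_c$order,
                   c("f1", "f2", "f3")[order(-(1 - rho), c("f1", "f2", "f3"))])
})

test_that("fold aggregation averages scores and re-breaks ties by name", {
  r1 <- small_ranking("m", c("a", "b"), c(1, 0))
  r2 <- small_ranking("m", c("a", "b"), c(0, 1))
  agg <- aggregate_over_folds(list(r1, r2))
  expect_equal(unname(agg$scores), c(0.5, 0.5))
  expect_identical(agg$order, c("a", "b"))   # tie broken alphabetically

  expect_identical(aggregate_over_folds(list(r1, r1))$scores, r1$scores)

  set.seed(8)
  folds <- lapply(1:5, function(i) small_ranking("m", letters[1:6], runif(6)))
  agg5 <- aggregate_over_folds(folds)
  direct <- rowMeans(sapply(folds, function(r) r$scores[letters[1:6]]))
  expect_equal(unname(agg5$scores[letters[1:6]]), unname(direct), tolerance = 1e-12)

  bad <- small_ranking("m", c("a", "z"), c(1, 2))
  expect_error(aggregate_over_folds(list(r1, bad)), "feature sets")
})
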