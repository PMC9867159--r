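#' Binary dropout mask
#'
#' Draws a multiplicative Bernoulli dropout mask with inverted scaling:
#' each entry is zero with probability `rho` (the drop rate) and
#' `1/(1-rho)` otherwise, so the mask has expectation one and no rescaling
#' is needed at prediction time.
#'
#' @param rho Drop probability in \[0, 1).
#' @param n Number of mask entries (use `prod(dim)` for a matrix and
#'   reshape).
#' @return Numeric vector of length `n` with entries in
#'   `{0, 1/(1-rho)}`. Uses the current RNG stream.
#' @export
binary_dropout_mask <- function(rho, n) {
  stopifnot(is.numeric(rho), length(rho) == 1, rho >= 0)
  if (rho >= 1) stop("rho = 1 would zero every unit; rho must be < 1")
  (stats::runif(n) >= rho) / (1 - rho)
}

#' Sample Gaussian variational-dropout weights
#'
#' Reparameterized draw from the variational posterior
#' `q(w) = N(theta, alpha * theta^2)`: `w = theta * (1 + sqrt(alpha) * eps)`
#' with `eps ~ N(0, 1)`, so that `Var(w) = alpha * theta^2`. The
#' multiplicative noise level `alpha` is the learned per-feature parameter;
#' large `alpha` marks a weight as noise.
#'
#' @param theta Numeric vector/matrix of weight means.
#' @param alpha Non-negative noise variances, recycled against `theta`.
#' @param eps Optional standard-normal draws of the same shape (for
#'   deterministic use); drawn from the current RNG stream if `NULL`.
#' @return Sampled weights, same shape as `theta`.
#' @export
sample_variational_weights <- function(theta, alpha, eps = NULL) {
  if (any(alpha < 0)) stop("alpha must be non-negative")
  if (is.null(eps)) eps <- stats::rnorm(length(theta))
  theta * (1 + sqrt(alpha) * eps)
}

#' Sample a concrete-relaxed dropout gate
#'
#' Draws the continuous relaxation of a Bernoulli drop indicator: the
#' drop-gate is `d = sigmoid((logit(rho) + log(eps) - log(1-eps)) / t)`
#' with `eps ~ U(0, 1)`; the returned keep-gate is `1 - d`. As the
#' temperature `t` decreases the gate approaches a hard Bernoulli draw
#' with drop probability `rho`.
#'
#' @param rho Drop probabilities in (0, 1).
#' @param t Temperature in (0, 1\].
#' @param eps Optional uniform draws (same length as `rho` after
#'   recycling); drawn from the current RNG stream if `NULL`.
#' @param n Number of draws when `rho` is scalar (default `length(rho)`).
#' @return Keep-gate values in (0, 1).
#' @export
sample_concrete_gate <- function(rho, t, eps = NULL, n = length(rho)) {
  if (any(rho <= 0) || any(rho >= 1)) stop("rho must lie strictly in (0, 1)")
  if (t <= 0 || t > 1) stop("temperature t must lie in (0, 1]; use a hard threshold for t = 0")
  if (is.null(eps)) eps <- stats::runif(n)
  d <- sigmoid((log(rho) - log(1 - rho) + log(eps) - log(1 - eps)) / t)
  1 - d
}

#' SGVB mini-batch objective
#'
#' The stochastic gradient variational Bayes estimator in minimization
#' form: the summed batch negative log-likelihood scaled up to the full
#' dataset size, plus the KL regularizer weighted by the annealing
#' multiplier `lambda`:
#' `loss = -(N/M) * sum(loglik) + lambda * kl_term`.
#'
#' @param loglik Per-sample log-likelihood terms of the mini-batch.
#' @param kl_term KL divergence of the variational posterior from the
#'   prior.
#' @param n_total Full dataset size N.
#' @param batch_size Mini-batch size M.
#' @param lambda Annealing multiplier in \[0, 1\].
#' @return Scalar loss.
#' @export
sgvb_objective <- function(loglik, kl_term, n_total, batch_size, lambda) {
  stopifnot(lambda >= 0, lambda <= 1, batch_size >= 1, n_total >= batch_size)
  if (!all(is.finite(loglik)) || !is.finite(kl_term)) {
    stop("non-finite objective terms")
  }
  -(n_total / batch_size) * sum(loglik) + lambda * kl_term
}

VKL_K <- c(0.63576, 1.87320, 1.48695)

#' KL regularizer for Gaussian variational dropout
#'
#' Sum over features of the log-uniform-prior KL approximation
#' `-(k1 * sigmoid(k2 + k3 * log(alpha)) - 0.5 * log(1 + 1/alpha) - k1)`
#' with `k1 = 0.63576`, `k2 = 1.87320`, `k3 = 1.48695`. Monotonically
#' decreasing in `log(alpha)` and approaching 0 as `alpha` grows, so
#' minimizing it drives noise levels up and features toward being dropped.
#'
#' @param log_alpha Numeric vector of per-feature log noise variances.
#' @return Scalar KL term.
#' @export
variational_kl <- function(log_alpha) {
  stopifnot(all(is.finite(log_alpha)))
  sum(variational_kl_terms(log_alpha))
}

variational_kl_terms <- function(log_alpha) {
  -(VKL_K[1] * sigmoid(VKL_K[2] + VKL_K[3] * log_alpha) -
      0.5 * log1p(exp(-log_alpha)) - VKL_K[1])
}

variational_kl_grad <- function(log_alpha) {
  s <- sigmoid(VKL_K[2] + VKL_K[3] * log_alpha)
  -VKL_K[1] * VKL_K[3] * s * (1 - s) - 0.5 * sigmoid(-log_alpha)
}

#' Active-feature penalty for concrete dropout
#'
#' Smooth count of the features not dropped out, used in place of the KL
#' term when the concrete gate is the feature selector:
#' `(1/D) * sum(Phi(rho_j))` where `Phi(rho)` is realized as the Bernoulli
#' drop-indicator CDF at zero, i.e. the keep probability `1 - rho`.
#' Minimizing it pushes drop probabilities toward one, penalizing the
#' number of features used.
#'
#' @param rho Drop probabilities in (0, 1).
#' @return Scalar penalty in (0, 1).
#' @export
concrete_penalty <- function(rho) {
  if (any(rho <= 0) || any(rho >= 1)) stop("rho must lie strictly in (0, 1)")
  mean(1 - rho)
}

#' Annealing schedule for the regularization multiplier
#'
#' Linear warm-up of the Lagrange multiplier on the regularizer:
#' `lambda = min(1, step * epoch)`, with the default step of 2.5e-3 per
#' epoch reaching 1 at epoch 400. Delaying the full penalty lets the
#' network learn a useful representation before features are pruned.
#'
#' @param epoch Zero-based epoch index.
#' @param step Increment per epoch (default 2.5e-3).
#' @return `lambda` in \[0, 1\].
#' @export
lambda_schedule <- function(epoch, step = 2.5e-3) {
  stopifnot(all(epoch >= 0))
  pmin(1, step * epoch)
}

#' Training configuration for the dropout selectors
#'
#' @param kind `"variational"` or `"concrete"`.
#' @param lr Learning rate; defaults to 1e-3 for the variational selector
#'   and 1e-2 for the concrete one.
#' @param betas Adam exponential-decay rates (default 0.9, 0.999).
#' @param epochs Training epochs (default 500).
#' @param batch_size Mini-batch size (default 32); a trailing remainder
#'   smaller than `min_batch` is merged into the previous batch.
#' @param min_batch Smallest allowed final batch (default 4).
#' @param lambda_step Annealing step per epoch (default 2.5e-3).
#' @param hidden Hidden-layer widths (default 64, 32).
#' @param hidden_dropout Ordinary dropout rate on the hidden layers
#'   (default 0.2).
#' @param weight_decay Decoupled L2 decay on the dense-layer weights
#'   (default 1e-3); keeps the classifier from memorizing small tables,
#'   which would hold irrelevant gates open.
#' @param tau Sparsification threshold on the effective drop probability
#'   (default 0.9, keep-inclusive).
#' @param temperature Concrete-gate temperature (default 0.5). Near-zero
#'   temperatures make the relaxation effectively discrete: the gates
#'   saturate and the drop-probability logits stop receiving likelihood
#'   gradient, stalling sparsification.
#' @param seed Integer seed.
#' @return A `train_config` list.
#' @export
train_config <- function(kind = c("variational", "concrete"), lr = NULL,
                         betas = c(0.9, 0.999), epochs = 500L,
                         batch_size = 32L, min_batch = 4L,
                         lambda_step = 2.5e-3, hidden = c(64L, 32L),
                         hidden_dropout = 0.2, weight_decay = 1e-3, tau = 0.9,
                         temperature = 0.5, seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(lr)) lr <- if (kind == "variational") 1e-3 else 1e-2
  stopifnot(lr > 0, epochs >= 1, batch_size >= 2, tau > 0, tau <= 1)
  list(kind = kind, lr = lr, betas = betas, epochs = as.integer(epochs),
       batch_size = as.integer(batch_size), min_batch = as.integer(min_batch),
       lambda_step = lambda_step, hidden = as.integer(hidden),
       hidden_dropout = hidden_dropout, weight_decay = weight_decay, tau = tau,
       temperature = temperature, seed = as.integer(seed))
}

# The variational gate is trained in the additive parameterization
# (theta, log sigma^2) with w = theta + sigma * eps, which is the same
# distribution as theta * (1 + sqrt(alpha) * eps) under
# alpha = sigma^2 / theta^2 but lets the noise-to-signal ratio alpha grow
# without bound as theta shrinks toward zero, which is what drives
# sparsification.
gate_log_alpha <- function(gate) {
  gate$log_sigma2 - log(gate$theta^2 + 1e-8)
}

# Effective drop probability of the current gate parameters.
selector_rho_eff <- function(state) {
  if (state$kind == "variational") {
    alpha <- exp(gate_log_alpha(state))
    alpha / (1 + alpha)
  } else {
    sigmoid(state$eta)
  }
}

# One mini-batch: loss and gradients for gate + dense parameters.
# `noise` carries pre-drawn gate noise and hidden dropout masks so the
# computation is a deterministic function of its inputs (used by the
# finite-difference tests as well as by the trainer).
selector_batch <- function(gate, mlp, x, yb, kind, cfg, lambda, n_total, noise) {
  m <- nrow(x)
  if (kind == "variational") {
    sigma <- exp(gate$log_sigma2 / 2)
    xg <- sweep(x, 2, gate$theta, "*") +
      sweep(x * noise$eps, 2, sigma, "*")
    scale <- n_total / m
  } else {
    lgt <- sweep(noise$logit_noise, 2, gate$eta, "+") / cfg$temperature
    d <- sigmoid(lgt)
    z <- 1 - d
    xg <- x * z
    scale <- 1 / m
  }
  net <- mlp_loss_grads(mlp, xg, yb, noise$masks, scale)

  if (kind == "variational") {
    la <- gate_log_alpha(gate)
    kl <- variational_kl(la)
    loss <- scale * net$nll_sum + lambda * kl
    dkl <- lambda * variational_kl_grad(la)
    g_theta <- colSums(net$dxg * x) +
      dkl * (-2 * gate$theta / (gate$theta^2 + 1e-8))
    g_ls <- colSums(net$dxg * x * noise$eps) * sigma / 2 + dkl
    gate_grads <- list(theta = g_theta, log_sigma2 = g_ls)
    reg <- kl
  } else {
    rho <- sigmoid(gate$eta)
    pen <- concrete_penalty(pmin(pmax(rho, 1e-12), 1 - 1e-12))
    loss <- scale * net$nll_sum + lambda * pen
    g_eta <- colSums(net$dxg * x * (-d * (1 - d) / cfg$temperature)) +
      lambda * (-rho * (1 - rho)) / length(rho)
    gate_grads <- list(eta = g_eta)
    reg <- pen
  }
  list(loss = loss, reg = reg, gate_grads = gate_grads, mlp_grads = net$grads)
}

draw_noise <- function(kind, m, d, hidden, hidden_dropout) {
  noise <- list()
  if (kind == "variational") {
    noise$eps <- matrix(stats::rnorm(m * d), m, d)
  } else {
    u <- matrix(stats::runif(m * d), m, d)
    noise$logit_noise <- log(u) - log(1 - u)
  }
  noise$masks <- lapply(hidden, function(hd) {
    matrix(binary_dropout_mask(hidden_dropout, m * hd), m, hd)
  })
  noise
}

#' Train a dropout feature selector
#'
#' Trains a small classifier whose first layer is a per-feature stochastic
#' gate — Gaussian variational dropout or a concrete-relaxed Bernoulli
#' gate — followed by two ReLU hidden layers with ordinary dropout and a
#' softmax head. The variational selector minimizes the SGVB objective
#' (scaled negative log-likelihood plus the log-uniform KL); the concrete
#' selector minimizes the mean negative log-likelihood plus the
#' active-feature penalty. In both cases the regularizer weight is
#' annealed linearly via [lambda_schedule()] so the network can fit the
#' data before sparsification pressure ramps up.
#'
#' @param x Numeric feature matrix (samples x features), ideally
#'   standardized.
#' @param y Two-level class factor (second level is the positive class).
#' @param config A [train_config()].
#' @return A `selector_state` list: gate parameters (`theta`,
#'   `log_sigma2` and the derived `log_alpha` for the variational kind;
#'   the drop-probability logit `eta` for the concrete kind), `kind`,
#'   feature names, the config, and a per-epoch `log` data.frame with
#'   `loss` (the annealed training loss actually optimized),
#'   `objective` (the same quantity evaluated with the regularizer at
#'   full weight, comparable across epochs because it does not move with
#'   the annealing schedule) and `sparse_rate`. The variational gate is trained in the
#'   additive parameterization `w = theta + sigma * eps` (the same
#'   posterior as the multiplicative form with
#'   `alpha = sigma^2 / theta^2`), which lets the noise-to-signal ratio
#'   grow without bound as an irrelevant feature's gate weight shrinks.
#' @export
train_selector <- function(x, y, config = train_config()) {
  x <- as.matrix(x)
  y <- factor(y)
  stopifnot(nlevels(y) == 2, nrow(x) == length(y))
  n <- nrow(x)
  d <- ncol(x)
  if (n < 2 * config$batch_size) {
    stop("need at least two mini-batches per epoch; reduce batch_size")
  }
  yb <- as.integer(y)  # 1/2 class index
  kind <- config$kind

  set.seed(config$seed)
  gate <- if (kind == "variational") {
    # log alpha starts at -8 (near-noiseless): sigma^2 = alpha * theta^2
    list(theta = rep(1, d), log_sigma2 = rep(-8, d))
  } else {
    list(eta = rep(log(0.1 / 0.9), d))
  }
  mlp <- mlp_init(d, config$hidden)
  opt_gate <- adam_init(gate)
  opt_mlp <- adam_init(mlp)

  log_loss <- numeric(config$epochs)
  log_obj <- numeric(config$epochs)
  log_sparse <- numeric(config$epochs)

  for (epoch in seq_len(config$epochs)) {
    lambda <- lambda_schedule(epoch - 1L, config$lambda_step)
    ord <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    ends <- pmin(starts + config$batch_size - 1L, n)
    if (length(starts) > 1L && (ends[length(ends)] - starts[length(starts)] + 1L) < config$min_batch) {
      starts <- starts[-length(starts)]
      ends[length(starts)] <- n
      ends <- ends[seq_along(starts)]
    }
    ep_loss <- 0
    ep_obj <- 0
    for (b in seq_along(starts)) {
      idx <- ord[starts[b]:ends[b]]
      xb <- x[idx, , drop = FALSE]
      noise <- draw_noise(kind, nrow(xb), d, config$hidden, config$hidden_dropout)
      step <- selector_batch(gate, mlp, xb, yb[idx], kind, config, lambda, n, noise)
      if (!is.finite(step$loss)) {
        stop(sprintf("non-finite loss at epoch %d", epoch))
      }
      ep_loss <- ep_loss + step$loss
      ep_obj <- ep_obj + step$loss + (1 - lambda) * step$reg
      up_g <- adam_step(gate, step$gate_grads, opt_gate, config$lr, config$betas)
      gate <- up_g$params
      opt_gate <- up_g$state
      up_m <- adam_step(mlp, step$mlp_grads, opt_mlp, config$lr, config$betas,
                        weight_decay = config$weight_decay)
      mlp <- up_m$params
      opt_mlp <- up_m$state
      if (kind == "variational") {
        gate$log_sigma2 <- pmin(pmax(gate$log_sigma2, -10), 10)
      } else {
        gate$eta <- pmin(pmax(gate$eta, -12), 12)
      }
    }
    state_now <- c(gate, list(kind = kind))
    log_loss[epoch] <- ep_loss / length(starts)
    log_obj[epoch] <- ep_obj / length(starts)
    log_sparse[epoch] <- mean(selector_rho_eff(state_now) > config$tau)
  }

  fn <- colnames(x)
  if (is.null(fn)) fn <- sprintf("F%03d", seq_len(d))
  if (kind == "variational") gate$log_alpha <- gate_log_alpha(gate)
  structure(c(gate, list(
    kind = kind, feature_names = fn, config = config, mlp = mlp,
    log = data.frame(epoch = seq_len(config$epochs), loss = log_loss,
                     objective = log_obj, sparse_rate = log_sparse)
  )), class = "selector_state")
}

new_ranking_result <- function(method, scores, keep, tau = NULL) {
  ord <- order(-scores, names(scores))
  structure(list(method = method,
                 scores = scores,
                 order = names(scores)[ord],
                 keep = keep,
                 sparse_rate = mean(!keep),
                 tau = tau),
            class = "ranking_result")
}

#' @export
print.ranking_result <- function(x, n = 10L, ...) {
  cat(sprintf("<ranking_result: %s>\n", x$method))
  cat(sprintf("  %d features, sparse rate %.3f\n", length(x$scores), x$sparse_rate))
  cat("  top:", paste(utils::head(x$order, n), collapse = ", "), "\n")
  invisible(x)
}

#' Rank features and apply the sparsification threshold
#'
#' Converts trained gate parameters into a feature ranking and a binary
#' keep mask. The effective drop probability is `rho` for the concrete
#' gate and `alpha / (1 + alpha)` for the variational gate (inverting
#' `alpha = rho / (1 - rho)`); the relevance score is `1 - rho_eff` and a
#' feature is kept when `rho_eff <= tau` (the threshold itself keeps,
#' dropping requires exceeding it).
#'
#' @param state A `selector_state` from [train_selector()].
#' @param tau Drop-probability threshold (default 0.9).
#' @return A `ranking_result` with per-feature scores, descending order,
#'   keep mask and sparse rate.
#' @export
rank_and_sparsify <- function(state, tau = 0.9) {
  rho_eff <- selector_rho_eff(state)
  scores <- stats::setNames(1 - rho_eff, state$feature_names)
  keep <- stats::setNames(rho_eff <= tau, state$feature_names)
  new_ranking_result(state$kind, scores, keep, tau = tau)
}

#' Average rankings over cross-validation folds
#'
#' Combines per-fold `ranking_result`s for the same feature set into one:
#' the relevance score of each feature is the mean of its per-fold scores,
#' the ordering is recomputed from the means (ties broken by feature
#' name), and the keep mask is re-derived (via the stored threshold for
#' gate selectors, otherwise nonzero mean score).
#'
#' @param results List of `ranking_result` objects over identical feature
#'   sets.
#' @return A single aggregated `ranking_result`.
#' @export
aggregate_over_folds <- function(results) {
  stopifnot(length(results) >= 1)
  fn <- names(results[[1]]$scores)
  for (r in results) {
    if (!setequal(names(r$scores), fn)) {
      stop("fold rankings cover different feature sets")
    }
  }
  scores <- rowMeans(vapply(results, function(r) r$scores[fn],
                            numeric(length(fn))))
  names(scores) <- fn
  tau <- results[[1]]$tau
  keep <- if (!is.null(tau)) (1 - scores) <= tau else scores > 0
  names(keep) <- fn
  new_ranking_result(results[[1]]$method, scores, keep, tau = tau)
}

#' Rank features of a feature table with any selector
#'
#' Cross-validated driver shared by all four ranking methods: for each
#' fold the training rows are z-scored (training-fold statistics) and the
#' chosen method is fitted on them; per-fold rankings are then averaged
#' with [aggregate_over_folds()].
#'
#' @param ft Feature table (see [feature_matrix()]).
#' @param folds Fold assignment from [make_folds()].
#' @param method `"variational"`, `"concrete"`, `"lasso"` or `"rf"`.
#' @param seed Root seed; each fold trains with `seed + fold`.
#' @param ... Extra arguments passed to the method ([train_config()]
#'   fields for the gate selectors, [lasso_rank()] / [rf_rank()] arguments
#'   otherwise).
#' @return Aggregated `ranking_result`.
#' @export
select_features <- function(ft, folds, method = c("variational", "concrete", "lasso", "rf"),
                            seed = 1L, ...) {
  method <- match.arg(method)
  x <- feature_matrix(ft)
  y <- feature_labels(ft)
  per_fold <- lapply(sort(unique(folds)), function(f) {
    tr <- which(folds != f)
    xs <- zscore_by_train(x, tr)[tr, , drop = FALSE]
    ys <- y[tr]
    fold_seed <- seed * 100L + f
    switch(method,
           variational = ,
           concrete = {
             cfg <- train_config(kind = method, seed = fold_seed, ...)
             rank_and_sparsify(train_selector(xs, ys, cfg), tau = cfg$tau)
           },
           lasso = lasso_fold_rank(xs, ys, seed = fold_seed, ...),
           rf = rf_fold_rank(xs, ys, seed = fold_seed, ...))
  })
  aggregate_over_folds(per_fold)
}
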