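# Minimal fully-connected network machinery for the dropout selectors:
# He-initialized dense layers, ReLU, softmax cross-entropy, hand-derived
# backprop and Adam. Kept internal; the exported surface is train_selector().

mlp_init <- function(d_in, hidden = c(64L, 32L), d_out = 2L) {
  sizes <- c(d_in, hidden, d_out)
  params <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    fan_in <- sizes[l]
    params[[paste0("W", l)]] <- matrix(stats::rnorm(fan_in * sizes[l + 1L],
                                                    sd = sqrt(2 / fan_in)),
                                       fan_in, sizes[l + 1L])
    params[[paste0("b", l)]] <- rep(0, sizes[l + 1L])
  }
  params
}

relu <- function(x) pmax(x, 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

# Forward + backward through the dense stack given gated inputs `xg`
# (M x D), one-hot free integer labels `yb` in {1, 2}, and pre-drawn hidden
# dropout masks (already inverted-scaled). Returns the summed per-sample
# negative log-likelihood, gradients for every dense parameter, and the
# gradient w.r.t. xg for the gate backward pass. `scale` multiplies the
# likelihood gradient (N/M for the SGVB estimator, 1/M for the mean form).
mlp_loss_grads <- function(params, xg, yb, masks, scale) {
  n_layers <- length(params) / 2L
  acts <- list(xg)
  pre <- list()
  h <- xg
  for (l in seq_len(n_layers)) {
    z <- h %*% params[[paste0("W", l)]] +
      matrix(params[[paste0("b", l)]], nrow(h), ncol(params[[paste0("W", l)]]),
             byrow = TRUE)
    pre[[l]] <- z
    if (l < n_layers) {
      h <- relu(z) * masks[[l]]
    } else {
      h <- z
    }
    acts[[l + 1L]] <- h
  }
  logits <- acts[[n_layers + 1L]]
  # stable log-softmax
  mx <- apply(logits, 1, max)
  lse <- mx + log(rowSums(exp(logits - mx)))
  picked <- logits[cbind(seq_len(nrow(logits)), yb)]
  nll_sum <- sum(lse - picked)

  probs <- exp(logits - lse)
  dlogits <- probs
  dlogits[cbind(seq_len(nrow(logits)), yb)] <-
    dlogits[cbind(seq_len(nrow(logits)), yb)] - 1
  dlogits <- dlogits * scale

  grads <- list()
  dh <- dlogits
  for (l in rev(seq_len(n_layers))) {
    grads[[paste0("W", l)]] <- crossprod(acts[[l]], dh)
    grads[[paste0("b", l)]] <- colSums(dh)
    if (l > 1L) {
      dh <- dh %*% t(params[[paste0("W", l)]])
      dh <- dh * masks[[l - 1L]] * (pre[[l - 1L]] > 0)
    } else {
      dxg <- dh %*% t(params[[paste0("W", 1L)]])
    }
  }
  list(nll_sum = nll_sum, grads = grads, dxg = dxg)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

# Adam with optional decoupled weight decay (applied to matrix-valued
# parameters only, i.e. dense weights, never biases or gate vectors).
adam_step <- function(params, grads, state, lr, betas = c(0.9, 0.999),
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  b1 <- betas[1]
  b2 <- betas[2]
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    if (weight_decay > 0 && is.matrix(params[[nm]])) {
      params[[nm]] <- params[[nm]] * (1 - lr * weight_decay)
    }
  }
  list(params = params, state = state)
}
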