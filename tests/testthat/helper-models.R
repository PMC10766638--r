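# Small builders shared across the suite.

# a compact network for dynamics/gradient tests
tiny_model <- function(n_inputs = 3, layers = 4, branches = 2,
                       recurrent = TRUE, seed = 3, u_th = 0.3,
                       init_alpha = "medium", init_gain = 4, ...) {
  cfg <- network_config(
    n_inputs = n_inputs, n_classes = 2, layer_sizes = layers,
    branches = branches, recurrent = recurrent, init_alpha = init_alpha,
    u_th = u_th, init_gain = init_gain, seed = seed, ...
  )
  build_network(cfg)
}

# spike-free regime: high threshold, weak drive, narrow surrogate so the
# pseudo-derivative vanishes far from threshold and the trajectory is smooth
subthreshold_model <- function(n_inputs = 3, layers = 4, branches = 2,
                               recurrent = TRUE, seed = 3) {
  m <- tiny_model(n_inputs, layers, branches, recurrent, seed = seed,
                  u_th = 5, init_gain = 1)
  m$config$surrogate <- surrogate_params(gamma = 0.5, h = 0, sigma = 0.05, s = 0)
  m
}

tiny_sample <- function(n_channels = 3, delay_ms = 10, seed = 1) {
  withr::with_seed(seed, {
    delayed_xor_sample(params = task_params(n_channels = n_channels,
                                            delay_ms = delay_ms))
  })
}

random_spikes <- function(T_len, C, p = 0.3, seed = 1) {
  withr::with_seed(seed, {
    spike_train(matrix(rbinom(T_len * C, 1, p), T_len, C))
  })
}

# independent single-compartment soft-reset LIF: forward trajectory plus full
# BPTT written directly from the collapsed recursions (used as the oracle for
# the D = 1, alpha = 0 degeneracy). Linear per-step readout, masked CE.
vanilla_soft_reference <- function(W, U, beta_raw, u_th, Wro, bro, x, labels,
                                   mask, sp) {
  x <- unclass(x)
  T_len <- nrow(x)
  n <- nrow(W)
  beta <- 1 / (1 + exp(-beta_raw))
  u <- matrix(0, T_len, n); o <- matrix(0, T_len, n); i <- matrix(0, T_len, n)
  u_prev <- numeric(n); o_prev <- numeric(n)
  for (t in seq_len(T_len)) {
    i_t <- as.numeric(W %*% x[t, ]) + as.numeric(U %*% o_prev)
    u_t <- beta * u_prev - o_prev * u_th + (1 - beta) * i_t
    o_t <- as.numeric(u_t - u_th >= 0)
    u[t, ] <- u_t; o[t, ] <- o_t; i[t, ] <- i_t
    u_prev <- u_t; o_prev <- o_t
  }
  # readout + loss
  drive <- o %*% t(Wro) + matrix(bro, T_len, length(bro), byrow = TRUE)
  pm <- exp(drive - apply(drive, 1, max))
  pm <- pm / rowSums(pm)
  n_mask <- sum(mask)
  loss <- mean(-log(pm[cbind(which(mask), labels[mask] + 1L)]))
  # backward
  Hq <- function(v) {
    out <- sp$gamma * (1 + sp$h) * dnorm(v, u_th, sp$sigma)
    if (sp$h > 0 && sp$s > 0) {
      out <- out - sp$gamma * sp$h * dnorm(v, sp$sigma, sp$s * sp$sigma) -
        sp$gamma * sp$h * dnorm(v, -sp$sigma, sp$s * sp$sigma)
    }
    out
  }
  gW <- matrix(0, n, ncol(W)); gU <- matrix(0, n, n)
  gbeta <- numeric(n)
  gWro <- matrix(0, nrow(Wro), ncol(Wro)); gbro <- numeric(length(bro))
  du_next <- numeric(n)
  for (t in seq(T_len, 1L)) {
    do_t <- numeric(n)
    if (mask[t]) {
      y <- numeric(nrow(Wro)); y[labels[t] + 1L] <- 1
      g <- (pm[t, ] - y) / n_mask
      gWro <- gWro + outer(g, o[t, ])
      gbro <- gbro + g
      do_t <- do_t + as.numeric(t(Wro) %*% g)
    }
    do_t <- do_t - u_th * du_next
    if (t < T_len) {
      # next-step synaptic input depends on o[t] through U
      do_t <- do_t + as.numeric(t(U) %*% ((1 - beta) * du_next))
    }
    du <- beta * du_next + Hq(u[t, ]) * do_t
    x_t <- x[t, ]
    o_prev <- if (t > 1) o[t - 1L, ] else numeric(n)
    u_prev <- if (t > 1) u[t - 1L, ] else numeric(n)
    gW <- gW + outer((1 - beta) * du, x_t)
    gU <- gU + outer((1 - beta) * du, o_prev)
    gbeta <- gbeta + beta * (1 - beta) * (u_prev - i[t, ]) * du
    du_next <- du
  }
  list(u = u, o = o, loss = loss,
       grads = list(W = gW, U = gU, beta_raw = gbeta, Wro = gWro, bro = gbro))
}
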