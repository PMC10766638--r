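# Hand-rolled backpropagation through time for DH-SNNs (reference path).
#
# Adjoint recursions, going backward in time and down the layer stack:
#   du[t]   = beta * du[t+1] (reset-adjusted) + H'(u[t]) * do[t]
#   di_d[t] = (1 - beta) * R * du[t] + alpha_d * di_d[t+1]
#   do[t]   = reset path into u[t+1]
#             + sum_d W_d(l+1)^T ((1 - alpha_d(l+1)) * di_d[t, l+1])
#             + sum_d U_d(l)^T  ((1 - alpha_d(l))  * di_d[t+1, l])
#             + readout/loss term at decision timesteps
# with zero adjoints beyond the last step. H' is the multi-Gaussian surrogate.
# The reset pathway is differentiated straight through (no detach).
# Parameter gradients accumulate over time; the timing-factor gradients carry
# the sigmoid chain factor alpha(1-alpha) / beta(1-beta).

new_zero_grads <- function(model) {
  layers <- lapply(model$layers, function(l) {
    list(
      W = lapply(seq_len(l$d), function(d) matrix(0, l$n, l$m)),
      U = if (!is.null(l$U)) lapply(seq_len(l$d), function(d) matrix(0, l$n, l$n)),
      alpha_raw = matrix(0, l$d, l$n),
      beta_raw = numeric(l$n)
    )
  })
  list(layers = layers,
       readout = list(W = matrix(0, nrow(model$readout$W), ncol(model$readout$W)),
                      b = numeric(length(model$readout$b))))
}

# per-timestep softmax probabilities of the linear readout
linear_readout_probs <- function(model, o_last) {
  T_len <- nrow(o_last)
  drive <- o_last %*% t(model$readout$W) +
    matrix(model$readout$b, T_len, length(model$readout$b), byrow = TRUE)
  softmax_rows(drive)
}

#' Backward pass over a recorded forward trajectory
#'
#' Runs the explicit BPTT adjoint recursions for every layer and timestep of
#' a recorded forward pass (see [forward()] with `record = TRUE`) and
#' accumulates parameter gradients. The loss is the masked cross-entropy of
#' the per-timestep linear readout; additional adjoint injections allow
#' arbitrary differentiable losses on states (used by [gradcheck()]).
#'
#' @param model a `dh_model` (readout kind `linear_per_step` for the built-in
#'   loss).
#' @param x `T x n_inputs` input matrix.
#' @param labels,mask per-timestep labels and decision mask (may be `NULL`
#'   when only injections drive the backward).
#' @param fwd optional pre-computed `forward(model, x, record = TRUE)`.
#' @param inject_u optional list per layer of `T x n` adjoint injections into
#'   the membrane potentials.
#' @param trace if `TRUE`, also return per-timestep L2 norms of the membrane
#'   and dendritic adjoints per layer.
#' @return list with `grads` (masked to branch supports), `loss`, `scores`,
#'   and optionally `trace`.
#' @export
dh_backward <- function(model, x, labels = NULL, mask = NULL, fwd = NULL,
                        inject_u = NULL, trace = FALSE) {
  x <- as_matrix(x)
  if (is.null(fwd)) fwd <- forward(model, x, record = TRUE)
  rec <- fwd$record
  if (is.null(rec)) stop("dh_backward: forward trajectory must be recorded",
                         call. = FALSE)
  T_len <- nrow(x)
  L <- length(model$layers)
  sp <- model$config$surrogate
  grads <- new_zero_grads(model)
  loss <- NULL
  scores <- NULL

  # loss injection into the top layer's spike adjoints
  inject_o_top <- matrix(0, T_len, model$layers[[L]]$n)
  if (!is.null(labels) && !is.null(mask) && any(mask)) {
    if (model$readout$kind != "linear_per_step") {
      stop("dh_backward: built-in loss supports the linear_per_step readout",
           call. = FALSE)
    }
    o_last <- fwd$spikes[[L]]
    scores <- linear_readout_probs(model, o_last)
    loss <- masked_loss(scores, labels, mask)
    n_mask <- sum(mask)
    for (t in which(mask)) {
      y <- numeric(ncol(scores)); y[labels[t] + 1L] <- 1
      g <- (scores[t, ] - y) / n_mask
      grads$readout$W <- grads$readout$W + outer(g, o_last[t, ])
      grads$readout$b <- grads$readout$b + g
      inject_o_top[t, ] <- inject_o_top[t, ] + as.numeric(t(model$readout$W) %*% g)
    }
  }

  # running adjoints at t+1 per layer
  du_next <- lapply(model$layers, function(l) numeric(l$n))
  di_next <- lapply(model$layers, function(l) matrix(0, l$d, l$n))
  tr <- if (trace) lapply(model$layers, function(l)
    list(du = numeric(T_len), di = numeric(T_len)))

  for (t in seq(T_len, 1L)) {
    di_t <- vector("list", L)
    du_t <- vector("list", L)
    for (l in seq(L, 1L)) {
      lay <- model$layers[[l]]
      alpha <- layer_alpha(lay)      # d x n
      beta <- layer_beta(lay)        # n
      u_t <- rec[[l]]$u[t, ]
      o_t <- fwd$spikes[[l]][t, ]
      o_prev <- if (t > 1) fwd$spikes[[l]][t - 1L, ] else numeric(lay$n)
      u_prev <- if (t > 1) rec[[l]]$u[t - 1L, ] else numeric(lay$n)
      i_t <- matrix(rec[[l]]$i[t, , ], lay$d, lay$n)
      i_prev <- if (t > 1) matrix(rec[[l]]$i[t - 1L, , ], lay$d, lay$n)
                else matrix(0, lay$d, lay$n)
      I_t <- matrix(rec[[l]]$I[t, , ], lay$d, lay$n)

      # --- do[t, l] ---
      do_t <- numeric(lay$n)
      if (l == L) do_t <- do_t + inject_o_top[t, ]
      # reset path into the own layer's next membrane potential
      do_t <- do_t + switch(lay$reset,
        soft = -lay$u_th * du_next[[l]],
        hard = -beta * u_t * du_next[[l]],
        none = 0
      )
      # feedforward path into the layer above at the same timestep
      if (l < L) {
        up <- model$layers[[l + 1L]]
        alpha_up <- layer_alpha(up)
        for (d in seq_len(up$d)) {
          do_t <- do_t +
            as.numeric(t(up$W[[d]]) %*% ((1 - alpha_up[d, ]) * di_t[[l + 1L]][d, ]))
        }
      }
      # recurrent path into the own layer's next-step currents
      if (!is.null(lay$U)) {
        for (d in seq_len(lay$d)) {
          do_t <- do_t +
            as.numeric(t(lay$U[[d]]) %*% ((1 - alpha[d, ]) * di_next[[l]][d, ]))
        }
      }

      # --- du[t, l] ---
      Hp <- surrogate_derivative(u_t, lay$u_th, sp)
      du_carry <- switch(lay$reset,
        soft = beta * du_next[[l]],
        none = beta * du_next[[l]],
        hard = beta * (1 - o_t) * du_next[[l]]
      )
      du <- du_carry + Hp * do_t
      if (!is.null(inject_u)) du <- du + inject_u[[l]][t, ]

      # --- di_d[t, l] ---
      di <- alpha * di_next[[l]] +
        matrix((1 - beta) * lay$R * du, lay$d, lay$n, byrow = TRUE)

      # --- parameter gradients at t ---
      x_below <- if (l == 1) x[t, ] else fwd$spikes[[l - 1L]][t, ]
      for (d in seq_len(lay$d)) {
        w_in <- (1 - alpha[d, ]) * di[d, ]
        grads$layers[[l]]$W[[d]] <- grads$layers[[l]]$W[[d]] + outer(w_in, x_below)
        if (!is.null(lay$U)) {
          # sum_t (1 - alpha) di[t+1] o[t]^T, shifted to pair di[t] with o[t-1]
          grads$layers[[l]]$U[[d]] <- grads$layers[[l]]$U[[d]] +
            outer(w_in, o_prev)
        }
      }
      if (lay$beta_learnable) {
        du_dbeta <- switch(lay$reset,
          soft = u_prev - lay$R * colSums(i_t),
          none = u_prev - lay$R * colSums(i_t),
          hard = (1 - o_prev) * u_prev - lay$R * colSums(i_t)
        )
        grads$layers[[l]]$beta_raw <- grads$layers[[l]]$beta_raw +
          beta * (1 - beta) * du_dbeta * du
      }
      if (lay$alpha_learnable) {
        grads$layers[[l]]$alpha_raw <- grads$layers[[l]]$alpha_raw +
          alpha * (1 - alpha) * (i_prev - I_t) * di
      }

      if (trace) {
        tr[[l]]$du[t] <- sqrt(sum(du^2))
        tr[[l]]$di[t] <- sqrt(sum(di^2))
      }
      du_t[[l]] <- du
      di_t[[l]] <- di
    }
    du_next <- du_t
    di_next <- di_t
  }

  # pruned synapses never receive gradient
  for (l in seq(L)) {
    lay <- model$layers[[l]]
    for (d in seq_len(lay$d)) {
      grads$layers[[l]]$W[[d]] <- grads$layers[[l]]$W[[d]] * lay$mask_W[[d]]
      if (!is.null(lay$U)) {
        grads$layers[[l]]$U[[d]] <- grads$layers[[l]]$U[[d]] * lay$mask_U[[d]]
      }
    }
  }
  out <- list(grads = grads, loss = loss, scores = scores)
  if (trace) out$trace <- tr
  out
}

#' Time-resolved adjoint magnitudes
#'
#' Runs one backward pass with tracing and returns, per layer, the L2 norm of
#' the membrane-potential adjoint and of the dendritic-current adjoint at
#' every timestep. Comparing how these decay while backpropagating across a
#' long delay shows why dendritic currents (never reset) carry gradients much
#' further than membrane potentials (periodically reset).
#'
#' @param model a `dh_model` with `linear_per_step` readout.
#' @param sample an `xor_sample`.
#' @return list per layer with numeric vectors `du` and `di` (length `T`).
#' @export
gradient_trace <- function(model, sample) {
  bw <- dh_backward(model, as_matrix(sample$spikes), labels = sample$labels,
                    mask = sample$decision_mask, trace = TRUE)
  bw$trace
}
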