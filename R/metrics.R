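#' Count model parameters
#'
#' Counts nonzero synaptic weights (branch supports only — under the balanced
#' disjoint restriction this is `N * M` per layer regardless of the number of
#' branches), learnable timing-factor scalars (`N * D` dendritic plus `N`
#' membrane per layer), and readout parameters.
#'
#' @param model a `dh_model`.
#' @param breakdown if `TRUE`, return the per-category counts.
#' @return total count (integer), or a list with `weights`, `timing`,
#'   `readout`, `total`.
#' @export
count_params <- function(model, breakdown = FALSE) {
  weights <- 0L; timing <- 0L
  for (lay in model$layers) {
    weights <- weights + sum(vapply(lay$mask_W, sum, numeric(1)))
    if (!is.null(lay$U)) {
      weights <- weights + sum(vapply(lay$mask_U, sum, numeric(1)))
    }
    if (lay$alpha_learnable) timing <- timing + lay$d * lay$n
    if (lay$beta_learnable) timing <- timing + lay$n
  }
  ro <- model$readout
  readout_n <- length(ro$W) + length(ro$b) +
    if (!is.null(ro$beta_raw)) length(ro$beta_raw) else 0L
  total <- as.integer(weights + timing + readout_n)
  if (!breakdown) return(total)
  list(weights = as.integer(weights), timing = as.integer(timing),
       readout = as.integer(readout_n), total = total)
}

# spikes-to-synapse fan-out per input index of one layer (feedforward or rec)
mask_fanout <- function(masks) {
  Reduce(`+`, lapply(masks, colSums))
}

#' Count event-driven synaptic operations
#'
#' One synaptic operation is one accumulate triggered by a presynaptic spike
#' across one valid (unpruned) synapse — the standard cost proxy on
#' event-driven neuromorphic hardware. Under balanced disjoint partitions
#' every input index feeds exactly one branch per neuron, so the count is
#' independent of the number of branches. Dendrite and soma state updates are
#' clock-driven and reported separately.
#'
#' @param model a `dh_model`.
#' @param spikes input `spike_train` (`T x n_inputs`).
#' @return list with `synaptic` (event-driven accumulations), `dendrite_updates`
#'   and `soma_updates` (clock-driven state updates).
#' @export
count_synops <- function(model, spikes) {
  x <- as_matrix(spikes)
  fwd <- forward(model, x)
  T_len <- nrow(x)
  syn <- 0
  below <- x
  for (l in seq_along(model$layers)) {
    lay <- model$layers[[l]]
    syn <- syn + sum(colSums(below) * mask_fanout(lay$mask_W))
    if (!is.null(lay$U)) {
      # recurrent input at step t is the layer's own raster at t-1
      own_prev <- rbind(0, fwd$spikes[[l]][-T_len, , drop = FALSE])
      syn <- syn + sum(colSums(own_prev) * mask_fanout(lay$mask_U))
    }
    below <- fwd$spikes[[l]]
  }
  # readout accumulates from the last layer's spikes
  syn <- syn + sum(colSums(below)) * nrow(model$readout$W)
  list(
    synaptic = syn,
    dendrite_updates = T_len * sum(vapply(model$layers,
                                          function(l) l$d * l$n, numeric(1))),
    soma_updates = T_len * sum(vapply(model$layers, function(l) l$n, numeric(1)))
  )
}

#' Accuracy under increasing input spike noise
#'
#' Evaluates a trained model on copies of the test set corrupted by
#' [inject_poisson_noise()] at each rate, repeating the (random) injection
#' `n_trials` times per rate. Rate 0 reproduces the clean accuracy exactly.
#'
#' @param model a trained `dh_model`.
#' @param samples test `xor_sample`s.
#' @param noise_rates numeric vector of noise rates (spikes/s per channel).
#' @param n_trials injections per rate.
#' @return data frame with `rate`, `accuracy_mean`, `accuracy_sd`.
#' @export
robustness_sweep <- function(model, samples, noise_rates, n_trials = 3) {
  rows <- lapply(noise_rates, function(rate) {
    accs <- vapply(seq_len(n_trials), function(k) {
      noisy <- lapply(samples, function(s) {
        s$spikes <- inject_poisson_noise(s$spikes, rate)
        s
      })
      evaluate(model, noisy)$accuracy
    }, numeric(1))
    data.frame(rate = rate, accuracy_mean = mean(accs),
               accuracy_sd = if (n_trials > 1) stats::sd(accs) else 0)
  })
  do.call(rbind, rows)
}
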