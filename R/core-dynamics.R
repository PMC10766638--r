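#' Clamp raw timing factors into (0, 1)
#'
#' Timing factors are the per-step geometric decay coefficients of dendritic
#' currents (alpha) and membrane potentials (beta). They are learned in raw,
#' unbounded form and soft-clamped through the logistic function on every
#' forward pass, so that the decay always stays strictly inside (0, 1).
#'
#' @param raw numeric vector/matrix of unbounded raw factors.
#' @return values `1 / (1 + exp(-raw))`, same shape as `raw`.
#' @export
clamp_timing <- function(raw) {
  stats::plogis(raw)
}

#' Inverse of [clamp_timing()]
#' @param p timing factors strictly inside (0, 1).
#' @return raw (logit) values.
#' @export
unclamp_timing <- function(p) {
  stats::qlogis(p)
}

#' One update of a dendritic current
#'
#' Each dendritic branch is a leaky integrator without any reset:
#' `i <- alpha * i_prev + (1 - alpha) * I`. With alpha near 1 the branch keeps
#' a long memory of past synaptic drive; with alpha near 0 it tracks the
#' instantaneous input.
#'
#' @param i_prev current at the previous step.
#' @param alpha timing factor(s) in `[0, 1]`, same shape as `i_prev` or scalar.
#' @param I synaptic input at the new step, same shape as `i_prev`.
#' @return the updated current.
#' @export
dendrite_step <- function(i_prev, alpha, I) {
  if (length(I) != length(i_prev)) {
    stop("dendrite_step: i_prev and I have different shapes", call. = FALSE)
  }
  if (length(alpha) != 1L && length(alpha) != length(i_prev)) {
    stop("dendrite_step: alpha does not broadcast over i_prev", call. = FALSE)
  }
  alpha * i_prev + (1 - alpha) * I
}

#' One update of the somatic membrane potential (soft reset)
#'
#' `u <- beta * u_prev + (1 - beta) * R * branch_sum - o_prev * u_th`.
#' The subtraction of the firing threshold is triggered by the *previous*
#' step's own spike and is not scaled by `(1 - beta)`: super-threshold residue
#' is preserved (soft reset).
#'
#' @param u_prev membrane potential at the previous step.
#' @param beta membrane timing factor(s) in `(0, 1)`.
#' @param branch_sum summed dendritic currents at the new step.
#' @param o_prev previous-step binary spikes.
#' @param u_th firing threshold (positive scalar).
#' @param R membrane resistance (default 1).
#' @return the updated membrane potential.
#' @export
soma_step <- function(u_prev, beta, branch_sum, o_prev, u_th, R = 1) {
  beta * u_prev + (1 - beta) * R * branch_sum - o_prev * u_th
}

#' Spike emission
#'
#' Heaviside threshold with the convention `H(0) = 1`: a neuron fires exactly
#' when its membrane potential reaches or exceeds the threshold.
#'
#' @param u membrane potential(s).
#' @param u_th firing threshold.
#' @return binary spikes, same shape as `u`.
#' @export
fire <- function(u, u_th) {
  as.numeric(u - u_th >= 0)
}

#' Fresh all-zero recurrent state of one layer
#'
#' @param n number of neurons.
#' @param d number of dendritic branches per neuron.
#' @return a `layer_state`: list with membrane potentials `u` (length `n`),
#'   dendritic currents `i` (`d x n` matrix) and output spikes `o` (length `n`).
#' @export
new_layer_state <- function(n, d) {
  structure(
    list(u = numeric(n), i = matrix(0, nrow = d, ncol = n), o = numeric(n)),
    class = "layer_state"
  )
}

#' One full layer timestep of DH-LIF dynamics
#'
#' Computes the per-branch synaptic input `I_d = W_d x + U_d o_prev` (the
#' recurrent term uses the layer's *own* spikes from the previous step), runs
#' [dendrite_step()] on every branch, updates the soma with the configured
#' reset mode using the previous step's spikes, and thresholds.
#'
#' Reset modes: `"soft"` subtracts `u_th` after a spike (the DH-LIF default),
#' `"hard"` multiplicatively clears the potential, `"none"` never resets.
#' Dendritic currents are never reset under any mode.
#'
#' @param state a `layer_state` (see [new_layer_state()]).
#' @param layer a `dh_layer` (see [dh_layer()]).
#' @param x feedforward input at the new step: binary spikes of the layer
#'   below, or real values for an encoding layer. Length must equal the
#'   layer's fan-in.
#' @return the new `layer_state`, with the per-branch synaptic input attached
#'   as attribute `"I"` (used by the backward pass).
#' @export
layer_step <- function(state, layer, x) {
  d <- layer$d
  n <- layer$n
  if (nrow(state$i) != d) {
    stop("layer_step: state has ", nrow(state$i), " branches, layer has ", d,
         call. = FALSE)
  }
  if (length(x) != layer$m) {
    stop("layer_step: input length ", length(x), " != layer fan-in ", layer$m,
         call. = FALSE)
  }
  alpha <- layer_alpha(layer)                     # d x n
  beta <- layer_beta(layer)                       # length n
  I <- matrix(0, nrow = d, ncol = n)
  for (dd in seq_len(d)) {
    I[dd, ] <- as.numeric(layer$W[[dd]] %*% x)
    if (!is.null(layer$U)) {
      I[dd, ] <- I[dd, ] + as.numeric(layer$U[[dd]] %*% state$o)
    }
  }
  i_new <- alpha * state$i + (1 - alpha) * I
  branch_sum <- colSums(i_new)
  u_new <- switch(layer$reset,
    soft = beta * state$u + (1 - beta) * layer$R * branch_sum -
      state$o * layer$u_th,
    hard = beta * (1 - state$o) * state$u + (1 - beta) * layer$R * branch_sum,
    none = beta * state$u + (1 - beta) * layer$R * branch_sum,
    stop("unknown reset mode: ", layer$reset, call. = FALSE)
  )
  o_new <- fire(u_new, layer$u_th)
  out <- structure(list(u = u_new, i = i_new, o = o_new), class = "layer_state")
  attr(out, "I") <- I
  out
}

#' One timestep of a single-compartment (vanilla) LIF layer
#'
#' The classic LIF ablations: the synaptic input `i = W x + U o_prev` drives
#' the membrane directly with no dendritic memory. Three reset mechanisms:
#' \describe{
#'   \item{hard}{`u <- beta * (1 - o_prev) * u_prev + (1 - beta) * i` — a spike
#'     clears the memorized potential completely.}
#'   \item{soft}{`u <- beta * u_prev - o_prev * u_th + (1 - beta) * i`.}
#'   \item{none}{`u <- beta * u_prev + (1 - beta) * i`.}
#' }
#' Written as standalone arithmetic (not via [layer_step()]) so it can serve
#' as an independent oracle for the degenerate DH-LIF configurations.
#'
#' @param state list with `u` and `o` (lengths `n`).
#' @param params list with `W` (`n x m`), optional `U` (`n x n`), `beta`
#'   (length `n` or scalar), `u_th` scalar.
#' @param x input vector at the new step (length `m`).
#' @param reset_mode one of `"hard"`, `"soft"`, `"none"`.
#' @return list with new `u`, `o` and the synaptic input `i`.
#' @export
vanilla_lif_step <- function(state, params, x, reset_mode = c("soft", "hard", "none")) {
  reset_mode <- match.arg(reset_mode)
  i_new <- as.numeric(params$W %*% x)
  if (!is.null(params$U)) i_new <- i_new + as.numeric(params$U %*% state$o)
  beta <- params$beta
  u_new <- switch(reset_mode,
    hard = beta * (1 - state$o) * state$u + (1 - beta) * i_new,
    soft = beta * state$u - state$o * params$u_th + (1 - beta) * i_new,
    none = beta * state$u + (1 - beta) * i_new
  )
  o_new <- fire(u_new, params$u_th)
  list(u = u_new, o = o_new, i = i_new)
}
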