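#' Construct one DH-LIF layer
#'
#' Holds per-branch masked feedforward (and optionally recurrent) weights,
#' raw timing factors, threshold and membrane resistance. Users normally build
#' whole models with [build_network()]; this constructor is exposed for small
#' hand-assembled examples and tests.
#'
#' @param n neurons in the layer.
#' @param m feedforward fan-in.
#' @param d dendritic branches per neuron.
#' @param W list of `d` weight matrices (`n x m`), zero outside the partition.
#' @param U optional list of `d` recurrent matrices (`n x n`).
#' @param mask_W,mask_U binary support masks matching `W` / `U`.
#' @param alpha_raw raw dendritic timing factors (`d x n`); clamped through the
#'   sigmoid on every forward step. Ignored when `alpha_fixed` is given.
#' @param beta_raw raw membrane timing factors (length `n`).
#' @param alpha_fixed optional `d x n` matrix of *clamped* alpha values frozen
#'   during training (e.g. all zeros for a vanilla single-compartment neuron).
#' @param beta_fixed optional frozen clamped beta values (length `n`).
#' @param alpha_learnable,beta_learnable should gradients be taken?
#' @param reset soma reset mode: `"soft"` (DH-LIF default), `"hard"`, `"none"`.
#' @param u_th firing threshold (> 0).
#' @param R membrane resistance.
#' @return a `dh_layer` list.
#' @export
dh_layer <- function(n, m, d, W, U = NULL, mask_W = NULL, mask_U = NULL,
                     alpha_raw = matrix(0, d, n), beta_raw = numeric(n),
                     alpha_fixed = NULL, beta_fixed = NULL,
                     alpha_learnable = TRUE, beta_learnable = TRUE,
                     reset = c("soft", "hard", "none"), u_th = 0.3, R = 1) {
  reset <- match.arg(reset)
  stopifnot(u_th > 0, length(W) == d)
  if (is.null(mask_W)) mask_W <- lapply(W, function(w) (w != 0) * 1)
  if (!is.null(U) && is.null(mask_U)) mask_U <- lapply(U, function(w) (w != 0) * 1)
  structure(list(
    n = as.integer(n), m = as.integer(m), d = as.integer(d),
    W = W, U = U, mask_W = mask_W, mask_U = mask_U,
    alpha_raw = alpha_raw, beta_raw = beta_raw,
    alpha_fixed = alpha_fixed, beta_fixed = beta_fixed,
    alpha_learnable = isTRUE(alpha_learnable) && is.null(alpha_fixed),
    beta_learnable = isTRUE(beta_learnable) && is.null(beta_fixed),
    reset = reset, u_th = u_th, R = R
  ), class = "dh_layer")
}

#' Clamped timing factors of a layer
#' @param layer a `dh_layer`.
#' @return `layer_alpha`: `d x n` matrix; `layer_beta`: length-`n` vector.
#' @export
layer_alpha <- function(layer) {
  if (!is.null(layer$alpha_fixed)) layer$alpha_fixed else clamp_timing(layer$alpha_raw)
}

#' @rdname layer_alpha
#' @export
layer_beta <- function(layer) {
  if (!is.null(layer$beta_fixed)) layer$beta_fixed else clamp_timing(layer$beta_raw)
}

init_range <- function(preset) {
  switch(preset,
    small = c(0.1, 0.5),
    medium = c(0.5, 0.9),
    large = c(0.9, 0.999),
    stop("unknown init preset: ", preset, call. = FALSE)
  )
}

#' Network configuration
#'
#' Collects every knob of a DH-SFNN / DH-SRNN experiment. Defaults describe
#' the networks used for the spiking XOR benchmarks: 64-neuron hidden layers,
#' one dendritic branch per neuron, threshold 0.3, multi-Gaussian surrogate,
#' per-timestep linear readout, Euler step of 1 ms.
#'
#' @param n_inputs,n_classes input channels and output classes.
#' @param layer_sizes integer vector of hidden-layer sizes.
#' @param branches branches per neuron, recycled over layers.
#' @param recurrent logical per layer (recycled): within-layer one-step-delayed
#'   recurrence.
#' @param init_alpha `"small"`, `"medium"` or `"large"`: the uniform range the
#'   clamped dendritic factors are initialized from — (0.1, 0.5), (0.5, 0.9)
#'   and (0.9, 0.999) respectively — mapped to raw space by the logit. May be a
#'   vector (recycled over layers) or a list of per-branch presets for a
#'   "beneficial" initialization with different timescales per branch.
#' @param init_beta preset for membrane factors (default `"medium"`).
#' @param alpha_learnable,beta_learnable learn the timing factors?
#' @param alpha_fixed optional clamped alpha value to freeze all branches at
#'   (e.g. `0` gives the vanilla single-compartment special case).
#' @param reset soma reset mode (`"soft"`, `"hard"`, `"none"`).
#' @param readout_kind `"linear_per_step"` (per-timestep linear decode, used by
#'   the XOR tasks), `"leaky_sum_softmax"` (sum over time of per-step softmax of
#'   a non-spiking leaky readout membrane), `"leaky_softmax_sum"` (softmax of
#'   the summed membrane), or `"spike_count"` (softmax over output spike
#'   counts of a spiking readout layer).
#' @param surrogate surrogate preset name or a [surrogate_params()].
#' @param u_th firing threshold.
#' @param R membrane resistance.
#' @param dt timestep (ms), bookkeeping only.
#' @param init_gain weight-initialization gain: per-branch weights are drawn
#'   uniform in `+/- init_gain / sqrt(fan-in of the branch)`. The default of 4
#'   puts hidden layers in a sparsely active regime at initialization despite
#'   the low-pass attenuation `(1 - alpha)(1 - beta)` between input and soma;
#'   with unit gain, networks initialized with large dendritic factors start
#'   nearly silent and optimization stalls.
#' @param partition_mode `"balanced_disjoint"`, `"sparsity_ratio"`, `"grouped"`.
#' @param sparsity connection sparsity ratio (only for `"sparsity_ratio"`).
#' @param group_size group size (only for `"grouped"`).
#' @param encoding_input if `TRUE`, the first layer accepts real-valued inputs
#'   while performing the same spiking dynamics.
#' @param seed integer seed making [build_network()] deterministic.
#' @return a `network_config` list.
#' @export
network_config <- function(n_inputs, n_classes, layer_sizes = 64,
                           branches = 1, recurrent = FALSE,
                           init_alpha = "large", init_beta = "medium",
                           alpha_learnable = TRUE, beta_learnable = TRUE,
                           alpha_fixed = NULL,
                           reset = c("soft", "hard", "none"),
                           readout_kind = c("linear_per_step", "leaky_sum_softmax",
                                            "leaky_softmax_sum", "spike_count"),
                           surrogate = "multi_gaussian",
                           u_th = 0.3, R = 1, dt = 1, init_gain = 4,
                           partition_mode = c("balanced_disjoint", "sparsity_ratio",
                                              "grouped"),
                           sparsity = NULL, group_size = 32,
                           encoding_input = FALSE, seed = NULL) {
  reset <- match.arg(reset)
  readout_kind <- match.arg(readout_kind)
  partition_mode <- match.arg(partition_mode)
  n_layers <- length(layer_sizes)
  stopifnot(n_inputs >= 1, n_classes >= 1, all(layer_sizes >= 1))
  if (is.character(surrogate)) surrogate <- surrogate_preset(surrogate)
  cfg <- list(
    n_inputs = as.integer(n_inputs), n_classes = as.integer(n_classes),
    layer_sizes = as.integer(layer_sizes),
    branches = as.integer(rep_len(branches, n_layers)),
    recurrent = rep_len(as.logical(recurrent), n_layers),
    init_alpha = if (is.list(init_alpha)) rep_len(init_alpha, n_layers)
                 else as.list(rep_len(init_alpha, n_layers)),
    init_beta = init_beta,
    alpha_learnable = isTRUE(alpha_learnable),
    beta_learnable = isTRUE(beta_learnable),
    alpha_fixed = alpha_fixed, reset = reset,
    readout_kind = readout_kind, surrogate = surrogate,
    u_th = u_th, R = R, dt = dt, init_gain = init_gain,
    partition_mode = partition_mode, sparsity = sparsity,
    group_size = as.integer(group_size),
    encoding_input = isTRUE(encoding_input), seed = seed
  )
  structure(cfg, class = "network_config")
}

draw_partition <- function(cfg, M, D, n) {
  switch(cfg$partition_mode,
    balanced_disjoint = partition_balanced(M, D, n_neurons = n),
    sparsity_ratio = partition_sparsity(M, D, cfg$sparsity, n_neurons = n),
    grouped = partition_grouped(n, M, D, group_size = cfg$group_size)
  )
}

# uniform +/- gain * |P_d|^(-1/2) per neuron-branch, zero off-support
init_branch_weights <- function(mask, gain = 1) {
  fanin <- rowSums(mask)
  fanin[fanin == 0] <- 1
  w <- matrix(stats::runif(length(mask), -1, 1), nrow(mask), ncol(mask))
  gain * w * mask / sqrt(fanin)
}

# raw timing factors drawn in clamped space, mapped back by the logit;
# `preset` is one name, or a vector of per-branch names
draw_alpha_raw <- function(preset, d, n) {
  out <- matrix(0, d, n)
  preset <- rep_len(preset, d)
  for (dd in seq_len(d)) {
    rg <- init_range(preset[dd])
    out[dd, ] <- unclamp_timing(stats::runif(n, rg[1], rg[2]))
  }
  out
}

#' Assemble a DH-SNN model
#'
#' Builds stacked DH-LIF layers (with per-neuron branch partitions and masked
#' weights) plus a readout, deterministically under `config$seed`. The vanilla
#' SNN is the special case of one branch per neuron with the dendritic factor
#' frozen at zero: the dendrite then passes input straight through and the
#' dynamics reduce to a single-compartment LIF with the configured reset.
#'
#' @param config a [network_config()].
#' @return a `dh_model`: list of `dh_layer`s, partitions, readout, config.
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "network_config"))
  builder <- function() {
    layers <- list()
    partitions <- list()
    m_prev <- config$n_inputs
    for (l in seq_along(config$layer_sizes)) {
      n <- config$layer_sizes[l]
      d <- config$branches[l]
      part_ff <- draw_partition(config, m_prev, d, n)
      mask_W <- materialize_masks(part_ff)
      W <- lapply(mask_W, init_branch_weights, gain = config$init_gain)
      U <- mask_U <- part_rec <- NULL
      if (config$recurrent[l]) {
        part_rec <- draw_partition(config, n, d, n)
        mask_U <- materialize_masks(part_rec)
        U <- lapply(mask_U, init_branch_weights, gain = config$init_gain)
      }
      alpha_fixed <- NULL
      if (!is.null(config$alpha_fixed)) {
        alpha_fixed <- matrix(config$alpha_fixed, d, n)
      }
      layers[[l]] <- dh_layer(
        n = n, m = m_prev, d = d, W = W, U = U,
        mask_W = mask_W, mask_U = mask_U,
        alpha_raw = draw_alpha_raw(config$init_alpha[[l]], d, n),
        beta_raw = unclamp_timing(stats::runif(n, init_range(config$init_beta)[1],
                                               init_range(config$init_beta)[2])),
        alpha_fixed = alpha_fixed,
        alpha_learnable = config$alpha_learnable,
        beta_learnable = config$beta_learnable,
        reset = config$reset, u_th = config$u_th, R = config$R
      )
      partitions[[l]] <- list(ff = part_ff, rec = part_rec)
      m_prev <- n
    }
    n_last <- config$layer_sizes[length(config$layer_sizes)]
    k <- config$n_classes
    readout <- list(
      kind = config$readout_kind,
      W = matrix(stats::runif(k * n_last, -1, 1), k, n_last) / sqrt(n_last),
      b = numeric(k)
    )
    if (readout$kind %in% c("leaky_sum_softmax", "leaky_softmax_sum", "spike_count")) {
      rg <- init_range(config$init_beta)
      readout$beta_raw <- unclamp_timing(stats::runif(k, rg[1], rg[2]))
    }
    structure(list(config = config, layers = layers, partitions = partitions,
                   readout = readout),
              class = "dh_model")
  }
  if (!is.null(config$seed)) withr::with_seed(config$seed, builder()) else builder()
}

#' Wrap hand-assembled layers into a model
#'
#' Lower-level companion of [build_network()] for tests and small examples:
#' takes explicit `dh_layer`s and a readout and attaches a minimal config.
#'
#' @param layers list of `dh_layer`s (fan-ins must chain).
#' @param readout list with `kind`, `W` (`n_classes x n_last`), `b`, and
#'   `beta_raw` for the leaky/spiking kinds.
#' @param surrogate a [surrogate_params()].
#' @param dt timestep in ms.
#' @return a `dh_model`.
#' @export
dh_model <- function(layers, readout, surrogate = surrogate_preset(), dt = 1) {
  for (l in seq_along(layers)[-1]) {
    if (layers[[l]]$m != layers[[l - 1]]$n) {
      stop("dh_model: fan-in of layer ", l, " does not match layer ", l - 1,
           call. = FALSE)
    }
  }
  n_last <- layers[[length(layers)]]$n
  stopifnot(ncol(readout$W) == n_last)
  config <- list(
    n_inputs = layers[[1]]$m, n_classes = nrow(readout$W),
    layer_sizes = vapply(layers, function(l) l$n, integer(1)),
    branches = vapply(layers, function(l) l$d, integer(1)),
    recurrent = vapply(layers, function(l) !is.null(l$U), logical(1)),
    readout_kind = readout$kind, surrogate = surrogate,
    u_th = layers[[1]]$u_th, R = layers[[1]]$R, dt = dt
  )
  class(config) <- "network_config"
  structure(list(config = config, layers = layers, partitions = NULL,
                 readout = readout),
            class = "dh_model")
}

#' @export
print.dh_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<dh_model> %d -> %s -> %d classes | branches %s | recurrent %s | readout %s\n",
    cfg$n_inputs, paste(cfg$layer_sizes, collapse = "-"), cfg$n_classes,
    paste(cfg$branches, collapse = ","),
    paste(substr(as.character(cfg$recurrent), 1, 1), collapse = ","),
    cfg$readout_kind
  ))
  cat(sprintf("  parameters: %d\n", count_params(x)))
  invisible(x)
}

#' Run a model over a spike train (reference path)
#'
#' Unrolls the layer dynamics over `t = 1..T` with all recurrent terms delayed
#' by one step and the initial state all zeros (the quiescent fixed point).
#' This is the plain-R reference used by tests, gradient checking and
#' visualization; training uses the compiled batched kernel, which is asserted
#' equal to this path.
#'
#' @param model a `dh_model`.
#' @param spikes `T x n_inputs` spike train (real-valued rows allowed when the
#'   model has an encoding first layer).
#' @param record if `TRUE`, also keep membrane potentials, dendritic currents
#'   and per-branch synaptic inputs for every layer and step.
#' @return list with `spikes` (list per layer of `T x n` binary rasters) and,
#'   if recorded, `u` (`T x n`), `i` and `I` (`T x d x n` arrays) per layer.
#' @export
forward <- function(model, spikes, record = FALSE) {
  x <- as_matrix(spikes)
  if (ncol(x) != model$config$n_inputs) {
    stop("forward: input has ", ncol(x), " channels, model expects ",
         model$config$n_inputs, call. = FALSE)
  }
  T_len <- nrow(x)
  n_layers <- length(model$layers)
  states <- lapply(model$layers, function(l) new_layer_state(l$n, l$d))
  rasters <- lapply(model$layers, function(l) matrix(0, T_len, l$n))
  rec <- NULL
  if (record) {
    rec <- lapply(model$layers, function(l) list(
      u = matrix(0, T_len, l$n),
      i = array(0, c(T_len, l$d, l$n)),
      I = array(0, c(T_len, l$d, l$n))
    ))
  }
  for (t in seq_len(T_len)) {
    inp <- x[t, ]
    for (l in seq_len(n_layers)) {
      states[[l]] <- layer_step(states[[l]], model$layers[[l]], inp)
      rasters[[l]][t, ] <- states[[l]]$o
      if (record) {
        rec[[l]]$u[t, ] <- states[[l]]$u
        rec[[l]]$i[t, , ] <- states[[l]]$i
        rec[[l]]$I[t, , ] <- attr(states[[l]], "I")
      }
      inp <- states[[l]]$o   # same-step spikes feed the layer above
    }
  }
  out <- list(spikes = rasters)
  if (record) out$record <- rec
  out
}
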