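softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

softmax_vec <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

#' Decode the last layer's spikes into class scores
#'
#' Readout variants:
#' \describe{
#'   \item{linear_per_step}{a linear layer emits per-timestep class
#'     probabilities `softmax(W o_t + b)` — the decode used by the spiking XOR
#'     tasks, where a decision is read off while the input unfolds.}
#'   \item{leaky_sum_softmax}{a non-spiking leaky accumulator (no fire, no
#'     reset) integrates `W o_t + b`; the per-step softmaxed membranes are
#'     averaged over time into one probability vector per sample.}
#'   \item{leaky_softmax_sum}{same accumulator, but the softmax is applied to
#'     the time-summed membrane.}
#'   \item{spike_count}{a spiking soft-reset readout layer; probabilities are
#'     the softmax of its per-class spike counts.}
#' }
#'
#' @param model a `dh_model`.
#' @param out_spikes `T x n` spike raster of the last hidden layer (from
#'   [forward()]).
#' @param labels optional labels (per masked timestep for `linear_per_step`,
#'   one per sample otherwise) used to also return the cross-entropy loss.
#' @param mask optional logical decision mask over timesteps (defaults to all).
#' @return a `readout_result`: list with `scores` (`T x n_classes` probability
#'   matrix for `linear_per_step`, otherwise a length-`n_classes` probability
#'   vector) and `loss` (`NULL` unless `labels` given).
#' @export
readout <- function(model, out_spikes, labels = NULL, mask = NULL) {
  ro <- model$readout
  o <- as_matrix(out_spikes)
  T_len <- nrow(o)
  drive <- o %*% t(ro$W) + matrix(ro$b, T_len, length(ro$b), byrow = TRUE)
  scores <- switch(ro$kind,
    linear_per_step = softmax_rows(drive),
    leaky_sum_softmax = ,
    leaky_softmax_sum = {
      beta <- clamp_timing(ro$beta_raw)
      u <- matrix(0, T_len, length(ro$b))
      uprev <- numeric(length(ro$b))
      for (t in seq_len(T_len)) {
        uprev <- beta * uprev + (1 - beta) * drive[t, ]
        u[t, ] <- uprev
      }
      if (ro$kind == "leaky_sum_softmax") colMeans(softmax_rows(u))
      else softmax_vec(colSums(u))
    },
    spike_count = {
      beta <- clamp_timing(ro$beta_raw)
      k <- length(ro$b)
      st <- list(u = numeric(k), o = numeric(k))
      counts <- numeric(k)
      for (t in seq_len(T_len)) {
        st <- vanilla_lif_step(st, list(W = ro$W, beta = beta,
                                        u_th = model$config$u_th),
                               o[t, ], reset_mode = "soft")
        counts <- counts + st$o
      }
      softmax_vec(counts)
    },
    stop("unknown readout kind: ", ro$kind, call. = FALSE)
  )
  loss <- NULL
  if (!is.null(labels)) {
    if (ro$kind == "linear_per_step") {
      loss <- masked_loss(scores, labels, if (is.null(mask)) rep(TRUE, T_len) else mask)
    } else {
      loss <- -log(max(scores[labels + 1L], 1e-12))
    }
  }
  structure(list(scores = scores, loss = loss, kind = ro$kind),
            class = "readout_result")
}

#' Cross-entropy over decision timesteps only
#'
#' The XOR tasks evaluate the network only inside decision windows; timesteps
#' outside the mask contribute nothing to the loss.
#'
#' @param scores `T x n_classes` matrix of class probabilities.
#' @param labels integer class labels in `0..n_classes-1`, length `T` (entries
#'   outside the mask may be `NA`).
#' @param mask logical vector of length `T`, `TRUE` at decision timesteps.
#' @return mean cross-entropy over masked timesteps.
#' @export
masked_loss <- function(scores, labels, mask) {
  mask <- as.logical(mask)
  if (!any(mask)) stop("masked_loss: decision mask is empty", call. = FALSE)
  idx <- which(mask)
  p <- scores[cbind(idx, labels[idx] + 1L)]
  mean(-log(pmax(p, 1e-12)))
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single archive holding weights, raw timing factors,
#' partitions and the full configuration; a reloaded model reproduces
#' bitwise-identical forward outputs.
#'
#' @param model a `dh_model`.
#' @param path file path (conventionally `.rds`).
#' @return `save_model`: the path, invisibly; `load_model`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "dh_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "dh_model"))
  model
}

#' Read a YAML experiment configuration
#'
#' Maps a flat YAML file onto [network_config()] arguments; unknown keys are
#' rejected to catch typos.
#'
#' @param path YAML file path.
#' @return a `network_config`.
#' @export
read_config_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(network_config))
  bad <- setdiff(names(vals), allowed)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  do.call(network_config, vals)
}
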