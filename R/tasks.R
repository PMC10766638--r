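#' Parameters of the spiking XOR task family
#'
#' The benchmarks encode a hidden binary choice as the firing rate of a
#' Bernoulli spike pattern: "high" fires with probability 0.6 per channel per
#' step, "low" with 0.2. Patterns last 10 ms at 1 ms resolution; in the
#' multi-timescale task consecutive fast patterns are separated by 5 ms
#' gaps; background noise spikes occur with probability 0.01 on every channel
#' throughout the trial.
#'
#' @param p_high,p_low firing probabilities of the high/low-rate patterns.
#' @param pattern_ms pattern duration (ms).
#' @param dt_ms simulation timestep (ms).
#' @param noise_p background spike probability per channel per step.
#' @param interval_ms gap between consecutive fast patterns (ms).
#' @param delay_ms delay of the delayed task (ms). The default of 50 is five
#'   membrane time constants beyond the largest medium-initialized membrane
#'   decay, long enough that a single-compartment network holds no usable
#'   trace of the first pattern.
#' @param n_repeats number of fast (Signal-2) patterns per multi-timescale
#'   sample.
#' @param n_channels channels per signal block.
#' @param decision_ms length of the decision window of the delayed task (ms).
#' @return a `task_params` list (durations converted to integer timesteps).
#' @export
task_params <- function(p_high = 0.6, p_low = 0.2, pattern_ms = 10, dt_ms = 1,
                        noise_p = 0.01, interval_ms = 5, delay_ms = 50,
                        n_repeats = 4, n_channels = 20, decision_ms = 10) {
  stopifnot(p_high >= 0, p_high <= 1, p_low >= 0, p_low <= 1,
            pattern_ms > 0, dt_ms > 0, noise_p >= 0, noise_p <= 1,
            interval_ms >= 0, delay_ms >= 0, n_repeats >= 1, n_channels >= 1)
  structure(list(
    p_high = p_high, p_low = p_low, dt_ms = dt_ms, noise_p = noise_p,
    pattern_steps = as.integer(round(pattern_ms / dt_ms)),
    interval_steps = as.integer(round(interval_ms / dt_ms)),
    delay_steps = as.integer(round(delay_ms / dt_ms)),
    decision_steps = as.integer(round(decision_ms / dt_ms)),
    n_repeats = as.integer(n_repeats), n_channels = as.integer(n_channels)
  ), class = "task_params")
}

rate_p <- function(rate_choice, params) {
  switch(rate_choice, high = params$p_high, low = params$p_low,
         stop("rate_choice must be 'low' or 'high'", call. = FALSE))
}

#' Draw one Bernoulli spike pattern
#'
#' @param rate_choice `"low"` or `"high"`.
#' @param params a [task_params()].
#' @param n_channels number of channels (defaults to `params$n_channels`).
#' @return a binary `spike_train` of `pattern_steps x n_channels`.
#' @export
gen_pattern <- function(rate_choice, params = task_params(),
                        n_channels = params$n_channels) {
  p <- rate_p(rate_choice, params)
  Tp <- params$pattern_steps
  m <- matrix(stats::rbinom(Tp * n_channels, 1, p), Tp, n_channels)
  spike_train(m, dt = params$dt_ms)
}

new_xor_sample <- function(spikes, labels, decision_mask, decision_id,
                           decision_labels, meta, params) {
  structure(list(
    spikes = spikes, labels = labels, decision_mask = decision_mask,
    decision_id = decision_id, decision_labels = decision_labels,
    meta = meta, params = params
  ), class = "xor_sample")
}

#' @export
print.xor_sample <- function(x, ...) {
  cat(sprintf("<xor_sample> %d steps x %d channels, %d decision(s), labels: %s\n",
              nrow(x$spikes), ncol(x$spikes), max(x$decision_id),
              paste(x$decision_labels, collapse = " ")))
  invisible(x)
}

xor_label <- function(rate_a, rate_b) {
  as.integer(xor(rate_a == "high", rate_b == "high"))
}

add_background_noise <- function(m, noise_p) {
  if (noise_p <= 0) return(m)
  noise <- matrix(stats::rbinom(length(m), 1, noise_p), nrow(m), ncol(m))
  pmax(m, noise)
}

#' Delayed spiking XOR sample
#'
#' Structure: an initial low- or high-rate pattern, a long noisy delay, a
#' second pattern, then a decision window during which the network must emit
#' `XOR(rate_1 is high, rate_2 is high)`. Both patterns share one channel
#' block; background noise covers the whole trial. The task probes how long a
#' network can hold a single bit.
#'
#' @param delay_ms delay between the two patterns (ms); defaults to
#'   `params$delay_steps * params$dt_ms`.
#' @param params a [task_params()].
#' @param rates optional length-2 character vector forcing the hidden
#'   rate choices (otherwise drawn uniformly).
#' @return an `xor_sample` with one decision window.
#' @export
delayed_xor_sample <- function(delay_ms = NULL, params = task_params(),
                               rates = NULL) {
  delay_steps <- if (is.null(delay_ms)) params$delay_steps
                 else as.integer(round(delay_ms / params$dt_ms))
  if (delay_steps < 0) stop("delay must be >= 0", call. = FALSE)
  if (is.null(rates)) rates <- sample(c("low", "high"), 2, replace = TRUE)
  Tp <- params$pattern_steps
  C <- params$n_channels
  T_len <- 2L * Tp + delay_steps + params$decision_steps
  m <- matrix(0, T_len, C)
  m[seq_len(Tp), ] <- as_matrix(gen_pattern(rates[1], params, C))
  t2 <- Tp + delay_steps
  m[t2 + seq_len(Tp), ] <- as_matrix(gen_pattern(rates[2], params, C))
  m <- add_background_noise(m, params$noise_p)
  label <- xor_label(rates[1], rates[2])
  mask <- rep(FALSE, T_len)
  mask[(t2 + Tp) + seq_len(params$decision_steps)] <- TRUE
  labels <- rep(NA_integer_, T_len)
  labels[mask] <- label
  decision_id <- integer(T_len)
  decision_id[mask] <- 1L
  new_xor_sample(spike_train(m, dt = params$dt_ms), labels, mask, decision_id,
                 label, meta = list(rates = rates, delay_steps = delay_steps),
                 params = params)
}

#' Multi-timescale spiking XOR sample
#'
#' A slow signal (Signal 1) appears once at the start on its own channel
#' block; a fast signal (Signal 2) then delivers `n_repeats` patterns on a
#' second block, separated by short gaps, with its rate redrawn independently
#' per repeat. As each fast pattern arrives the network must emit
#' `XOR(Signal-1 rate, current Signal-2 rate)`, so it has to memorize the slow
#' component while tracking the fast one — the signature of multi-timescale
#' processing.
#'
#' @param n_repeats number of Signal-2 patterns (defaults to
#'   `params$n_repeats`).
#' @param params a [task_params()].
#' @param rates optional forced rates: list with `s1` (one choice) and `s2`
#'   (length `n_repeats`).
#' @return an `xor_sample` with `n_repeats` decision windows; channels
#'   `1..n_channels` carry Signal 1, the rest Signal 2.
#' @export
multiscale_xor_sample <- function(n_repeats = NULL, params = task_params(),
                                  rates = NULL) {
  if (is.null(n_repeats)) n_repeats <- params$n_repeats
  stopifnot(n_repeats >= 1)
  Tp <- params$pattern_steps
  gap <- params$interval_steps
  C <- params$n_channels
  if (is.null(rates)) {
    rates <- list(s1 = sample(c("low", "high"), 1),
                  s2 = sample(c("low", "high"), n_repeats, replace = TRUE))
  }
  T_len <- Tp + n_repeats * (Tp + gap)
  m <- matrix(0, T_len, 2L * C)
  m[seq_len(Tp), seq_len(C)] <- as_matrix(gen_pattern(rates$s1, params, C))
  mask <- rep(FALSE, T_len)
  labels <- rep(NA_integer_, T_len)
  decision_id <- integer(T_len)
  decision_labels <- integer(n_repeats)
  for (r in seq_len(n_repeats)) {
    start <- Tp + (r - 1L) * (Tp + gap) + gap
    idx <- start + seq_len(Tp)
    m[idx, C + seq_len(C)] <- as_matrix(gen_pattern(rates$s2[r], params, C))
    lab <- xor_label(rates$s1, rates$s2[r])
    mask[idx] <- TRUE
    labels[idx] <- lab
    decision_id[idx] <- r
    decision_labels[r] <- lab
  }
  m <- add_background_noise(m, params$noise_p)
  new_xor_sample(spike_train(m, dt = params$dt_ms), labels, mask, decision_id,
                 decision_labels, meta = list(rates = rates), params = params)
}

#' Generate a dataset of XOR samples
#'
#' @param n number of samples.
#' @param task `"multiscale"` or `"delayed"`.
#' @param params a [task_params()].
#' @param ... passed to the per-sample generator.
#' @return list of `xor_sample`s (all sharing one temporal layout).
#' @export
xor_dataset <- function(n, task = c("multiscale", "delayed"),
                        params = task_params(), ...) {
  task <- match.arg(task)
  gen <- switch(task, multiscale = multiscale_xor_sample,
                delayed = delayed_xor_sample)
  lapply(seq_len(n), function(i) gen(params = params, ...))
}

#' Overlay Poisson spike noise on a spike train
#'
#' Independent Bernoulli noise with per-bin probability `rate * dt` is OR-ed
#' into the train: original spikes are never deleted, so the noisy train
#' dominates the clean one elementwise.
#'
#' @param spikes a `spike_train`.
#' @param rate noise rate in spikes per second per channel.
#' @return the noisy `spike_train`.
#' @export
inject_poisson_noise <- function(spikes, rate) {
  stopifnot(rate >= 0)
  if (rate == 0) return(spikes)
  dt_s <- attr(spikes, "dt") / 1000
  p <- min(1, rate * dt_s)
  m <- as_matrix(spikes)
  noise <- matrix(stats::rbinom(length(m), 1, p), nrow(m), ncol(m))
  spike_train(pmax(m, noise), dt = attr(spikes, "dt"))
}

#' Two-timescale demonstration drive
#'
#' A qualitative input for illustrating dendritic bursting: one channel block
#' carries a fast periodic drive (a spike every `drive_period` steps), the
#' other a slow on/off modulation (solid spiking during the "on" half of each
#' `modulator_period`). A two-branch neuron with a fast branch on the drive
#' and a slow branch on the modulator fires isolated drive-locked spikes that
#' are grouped into bursts by the slow envelope.
#'
#' @param params a [task_params()] (channels per block from `n_channels`).
#' @param T_steps total duration in steps.
#' @param drive_period steps between drive spikes.
#' @param modulator_period on/off cycle length of the modulator block.
#' @return a `spike_train` of `T_steps x (2 * n_channels)`; drive block first.
#' @export
bursting_demo_inputs <- function(params = task_params(), T_steps = 200,
                                 drive_period = 3, modulator_period = 100) {
  stopifnot(modulator_period > drive_period)
  C <- params$n_channels
  m <- matrix(0, T_steps, 2L * C)
  drive_times <- seq(drive_period, T_steps, by = drive_period)
  m[drive_times, seq_len(C)] <- 1
  phase <- ((seq_len(T_steps) - 1) %% modulator_period) < modulator_period / 2
  m[phase, C + seq_len(C)] <- 1
  spike_train(m, dt = params$dt_ms)
}

#' Export / import XOR samples in a sparse units/times layout
#'
#' Serializes samples as per-sample sparse spike lists (`units`: 0-based
#' channel index per spike; `times`: spike time in ms) plus labels, masks and
#' metadata — the layout used by event-based speech datasets such as SHD —
#' as JSON text. A converted SHD-style file with the same fields can be read
#' back through the same reader.
#'
#' @param samples list of `xor_sample`s.
#' @param path output JSON path.
#' @return `export_samples_json`: `path` invisibly; `import_samples_json`: the
#'   reconstructed list of `xor_sample`s.
#' @export
export_samples_json <- function(samples, path) {
  payload <- lapply(samples, function(s) {
    m <- as_matrix(s$spikes)
    hits <- which(m != 0, arr.ind = TRUE)
    list(
      units = as.integer(hits[, 2] - 1L),
      times = as.numeric((hits[, 1] - 1L) * attr(s$spikes, "dt")),
      n_steps = nrow(m), n_channels = ncol(m), dt = attr(s$spikes, "dt"),
      labels = ifelse(is.na(s$labels), -1L, s$labels),
      decision_id = s$decision_id,
      decision_labels = s$decision_labels,
      meta = s$meta
    )
  })
  jsonlite::write_json(payload, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname export_samples_json
#' @export
import_samples_json <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(payload, function(s) {
    m <- matrix(0, s$n_steps[[1]], s$n_channels[[1]])
    units <- as.integer(unlist(s$units))
    steps <- as.integer(round(as.numeric(unlist(s$times)) / s$dt[[1]]))
    if (length(units)) m[cbind(steps + 1L, units + 1L)] <- 1
    labels <- as.integer(unlist(s$labels))
    labels[labels < 0] <- NA_integer_
    decision_id <- as.integer(unlist(s$decision_id))
    new_xor_sample(
      spike_train(m, dt = s$dt[[1]]), labels, decision_id > 0L, decision_id,
      as.integer(unlist(s$decision_labels)),
      meta = s$meta, params = NULL
    )
  })
}
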