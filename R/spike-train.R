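#' Construct a spike train
#'
#' A spike train is a dense numeric matrix with one row per timestep and one
#' column per input channel, holding 0/1 spike indicators. It is the universal
#' input/output currency of the package. Real-valued entries are permitted so
#' that the first layer of a network can act as an encoding layer for
#' non-spiking data; generators in this package always emit binary trains.
#'
#' @param x numeric matrix, timesteps in rows, channels in columns.
#' @param dt timestep length in milliseconds (default 1 ms).
#' @param binary if `TRUE` (default), entries must be 0 or 1.
#' @return a `spike_train`: the matrix with a `dt` attribute.
#' @export
spike_train <- function(x, dt = 1, binary = TRUE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (binary && !all(x %in% c(0, 1))) {
    stop("spike train entries must be 0 or 1", call. = FALSE)
  }
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("dt must be a positive scalar (ms)", call. = FALSE)
  }
  structure(x, dt = dt, class = c("spike_train", "matrix", "array"))
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf(
    "<spike_train> %d timesteps x %d channels, dt = %g ms, %d spikes (rate %.3f)\n",
    nrow(x), ncol(x), attr(x, "dt"), sum(x != 0), mean(x != 0)
  ))
  invisible(x)
}

#' Number of timesteps / channels of a spike train
#' @param x a `spike_train` or matrix.
#' @return integer count.
#' @export
n_timesteps <- function(x) nrow(x)

#' @rdname n_timesteps
#' @export
n_channels <- function(x) ncol(x)

# strip class/attributes for raw matrix maths
as_matrix <- function(x) {
  attr(x, "dt") <- NULL
  class(x) <- NULL
  dim(x) <- dim(as.matrix(x))
  x <- unclass(x)
  matrix(as.numeric(x), nrow = NROW(x), ncol = NCOL(x))
}
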