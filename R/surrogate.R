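#' Surrogate (pseudo-derivative) parameters
#'
#' The spike nonlinearity is a Heaviside step, whose derivative is replaced
#' during backpropagation by a soft multi-Gaussian curve: a positive Gaussian
#' of width `sigma` peaked at the firing threshold, minus two negative side
#' lobes of relative height `h` and width `s * sigma` centred at `+sigma` and
#' `-sigma`. `gamma` scales the overall magnitude.
#'
#' Presets:
#' \describe{
#'   \item{`"multi_gaussian"`}{`gamma, h, sigma, s = 0.5, 0.15, 0.5, 6` — the
#'     default used for the spiking XOR and speech-style tasks.}
#'   \item{`"single_gaussian"`}{`gamma, h, sigma, s = 0.5, 0, 0.5, 0` — no side
#'     lobes (used for pixel-sequence benchmarks).}
#' }
#'
#' @param gamma magnitude factor (> 0).
#' @param h side-lobe magnitude factor (>= 0).
#' @param sigma width of the central Gaussian (> 0).
#' @param s side-lobe width factor (>= 0; `0` together with `h = 0` means no
#'   side lobes).
#' @return a `surrogate_params` list.
#' @export
surrogate_params <- function(gamma = 0.5, h = 0.15, sigma = 0.5, s = 6) {
  stopifnot(gamma > 0, sigma > 0, s >= 0, h >= 0)
  structure(list(gamma = gamma, h = h, sigma = sigma, s = s),
            class = "surrogate_params")
}

#' @rdname surrogate_params
#' @param preset name of a preset.
#' @export
surrogate_preset <- function(preset = c("multi_gaussian", "single_gaussian")) {
  preset <- match.arg(preset)
  switch(preset,
    multi_gaussian = surrogate_params(0.5, 0.15, 0.5, 6),
    single_gaussian = surrogate_params(0.5, 0, 0.5, 0)
  )
}

#' Multi-Gaussian surrogate derivative of the spike function
#'
#' Evaluates
#' `gamma * (1 + h) * N(u | u_th, sigma^2) - gamma * h * N(u | sigma, (s*sigma)^2)
#'  - gamma * h * N(u | -sigma, (s*sigma)^2)`
#' with `N` the Gaussian density. The peak sits at the firing threshold; the
#' side lobes give the curve a slight negative surround. This value stands in
#' for `H'` wherever the spike function is differentiated.
#'
#' @param u membrane potential(s).
#' @param u_th firing threshold.
#' @param sp a `surrogate_params`.
#' @return pseudo-derivative values, same shape as `u`.
#' @export
surrogate_derivative <- function(u, u_th, sp = surrogate_preset()) {
  out <- sp$gamma * (1 + sp$h) * stats::dnorm(u, mean = u_th, sd = sp$sigma)
  if (sp$h > 0 && sp$s > 0) {
    out <- out -
      sp$gamma * sp$h * stats::dnorm(u, mean = sp$sigma, sd = sp$s * sp$sigma) -
      sp$gamma * sp$h * stats::dnorm(u, mean = -sp$sigma, sd = sp$s * sp$sigma)
  }
  out
}

#' Smoothed spike function (antiderivative of the surrogate)
#'
#' The exact antiderivative of [surrogate_derivative()], built from Gaussian
#' CDFs. Replacing the Heaviside by this smooth function yields the
#' "surrogate-smoothed" forward pass whose true gradient the hand-rolled
#' backward recursions must reproduce; it is what the finite-difference
#' gradient oracle differentiates.
#'
#' @inheritParams surrogate_derivative
#' @return smoothed spike values, same shape as `u`.
#' @export
surrogate_spike <- function(u, u_th, sp = surrogate_preset()) {
  out <- sp$gamma * (1 + sp$h) * stats::pnorm(u, mean = u_th, sd = sp$sigma)
  if (sp$h > 0 && sp$s > 0) {
    out <- out -
      sp$gamma * sp$h * stats::pnorm(u, mean = sp$sigma, sd = sp$s * sp$sigma) -
      sp$gamma * sp$h * stats::pnorm(u, mean = -sp$sigma, sd = sp$s * sp$sigma)
  }
  out
}
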