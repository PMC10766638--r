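# Flat views of a model's learnable parameters. Order: per layer W_1..W_D,
# U_1..U_D, alpha_raw, beta_raw (learnable only), then readout W, b. Weight
# entries outside the branch support are excluded (they are structurally 0).

param_template <- function(model) {
  out <- list()
  for (l in seq_along(model$layers)) {
    lay <- model$layers[[l]]
    for (d in seq_len(lay$d)) {
      out[[length(out) + 1L]] <- list(layer = l, kind = "W", branch = d,
                                      idx = which(lay$mask_W[[d]] != 0))
    }
    if (!is.null(lay$U)) {
      for (d in seq_len(lay$d)) {
        out[[length(out) + 1L]] <- list(layer = l, kind = "U", branch = d,
                                        idx = which(lay$mask_U[[d]] != 0))
      }
    }
    if (lay$alpha_learnable) {
      out[[length(out) + 1L]] <- list(layer = l, kind = "alpha_raw",
                                      idx = seq_along(lay$alpha_raw))
    }
    if (lay$beta_learnable) {
      out[[length(out) + 1L]] <- list(layer = l, kind = "beta_raw",
                                      idx = seq_along(lay$beta_raw))
    }
  }
  out[[length(out) + 1L]] <- list(layer = NA, kind = "readout_W",
                                  idx = seq_along(model$readout$W))
  out[[length(out) + 1L]] <- list(layer = NA, kind = "readout_b",
                                  idx = seq_along(model$readout$b))
  out
}

slot_get <- function(model, slot) {
  switch(slot$kind,
    W = model$layers[[slot$layer]]$W[[slot$branch]][slot$idx],
    U = model$layers[[slot$layer]]$U[[slot$branch]][slot$idx],
    alpha_raw = model$layers[[slot$layer]]$alpha_raw[slot$idx],
    beta_raw = model$layers[[slot$layer]]$beta_raw[slot$idx],
    readout_W = model$readout$W[slot$idx],
    readout_b = model$readout$b[slot$idx]
  )
}

slot_set <- function(model, slot, values) {
  switch(slot$kind,
    W = model$layers[[slot$layer]]$W[[slot$branch]][slot$idx] <- values,
    U = model$layers[[slot$layer]]$U[[slot$branch]][slot$idx] <- values,
    alpha_raw = model$layers[[slot$layer]]$alpha_raw[slot$idx] <- values,
    beta_raw = model$layers[[slot$layer]]$beta_raw[slot$idx] <- values,
    readout_W = model$readout$W[slot$idx] <- values,
    readout_b = model$readout$b[slot$idx] <- values
  )
  model
}

slot_get_grad <- function(grads, slot) {
  switch(slot$kind,
    W = grads$layers[[slot$layer]]$W[[slot$branch]][slot$idx],
    U = grads$layers[[slot$layer]]$U[[slot$branch]][slot$idx],
    alpha_raw = grads$layers[[slot$layer]]$alpha_raw[slot$idx],
    beta_raw = grads$layers[[slot$layer]]$beta_raw[slot$idx],
    readout_W = grads$readout$W[slot$idx],
    readout_b = grads$readout$b[slot$idx]
  )
}

#' Flatten / restore learnable parameters
#'
#' @param model a `dh_model`.
#' @return `flatten_params`: numeric vector of all learnable parameters
#'   (masked weight entries excluded); `unflatten_params`: the model with
#'   parameters replaced by `values`.
#' @export
flatten_params <- function(model) {
  unlist(lapply(param_template(model), function(s) slot_get(model, s)))
}

#' @rdname flatten_params
#' @param values numeric vector as produced by `flatten_params`.
#' @export
unflatten_params <- function(model, values) {
  tpl <- param_template(model)
  pos <- 0L
  for (s in tpl) {
    k <- length(s$idx)
    model <- slot_set(model, s, values[pos + seq_len(k)])
    pos <- pos + k
  }
  stopifnot(pos == length(values))
  model
}

flatten_grads <- function(model, grads) {
  unlist(lapply(param_template(model), function(s) slot_get_grad(grads, s)))
}

# group label per flat parameter, for per-group error reporting
param_groups <- function(model) {
  tpl <- param_template(model)
  unlist(lapply(tpl, function(s) {
    rep(if (is.na(s$layer)) s$kind else paste0("L", s$layer, "_", s$kind),
        length(s$idx))
  }))
}

# ---- forward-mode (tangent) sweep through the straight-through graph ----
# Propagates directional derivatives of all states along a parameter tangent
# v and returns the directional derivative of the masked CE loss. The spike
# nonlinearity is linearized with the same multi-Gaussian pseudo-derivative
# the reverse pass uses, so this is the forward-mode twin of dh_backward:
# the two must agree to float precision.
loss_tangent <- function(model, x, labels, mask, tangent) {
  x <- as_matrix(x)
  T_len <- nrow(x)
  L <- length(model$layers)
  sp <- model$config$surrogate
  tv <- unflatten_params(new_zero_model(model), tangent)

  states <- lapply(model$layers, function(l) new_layer_state(l$n, l$d))
  dstates <- lapply(model$layers, function(l) new_layer_state(l$n, l$d))
  o_last <- matrix(0, T_len, model$layers[[L]]$n)
  do_last <- matrix(0, T_len, model$layers[[L]]$n)

  for (t in seq_len(T_len)) {
    inp <- x[t, ]; dinp <- numeric(length(inp))
    for (l in seq_len(L)) {
      lay <- model$layers[[l]]
      tl <- tv$layers[[l]]
      alpha <- layer_alpha(lay); beta <- layer_beta(lay)
      dalpha <- if (lay$alpha_learnable) alpha * (1 - alpha) * tl$alpha_raw
                else matrix(0, lay$d, lay$n)
      dbeta <- if (lay$beta_learnable) beta * (1 - beta) * tl$beta_raw
               else numeric(lay$n)
      st <- states[[l]]; dst <- dstates[[l]]
      I <- dI <- matrix(0, lay$d, lay$n)
      for (d in seq_len(lay$d)) {
        I[d, ] <- as.numeric(lay$W[[d]] %*% inp)
        dI[d, ] <- as.numeric(tl$W[[d]] %*% inp + lay$W[[d]] %*% dinp)
        if (!is.null(lay$U)) {
          I[d, ] <- I[d, ] + as.numeric(lay$U[[d]] %*% st$o)
          dI[d, ] <- dI[d, ] + as.numeric(tl$U[[d]] %*% st$o + lay$U[[d]] %*% dst$o)
        }
      }
      i_new <- alpha * st$i + (1 - alpha) * I
      di_new <- alpha * dst$i + (1 - alpha) * dI + dalpha * (st$i - I)
      bsum <- colSums(i_new); dbsum <- colSums(di_new)
      u_new <- switch(lay$reset,
        soft = beta * st$u + (1 - beta) * lay$R * bsum - st$o * lay$u_th,
        hard = beta * (1 - st$o) * st$u + (1 - beta) * lay$R * bsum,
        none = beta * st$u + (1 - beta) * lay$R * bsum
      )
      du_new <- switch(lay$reset,
        soft = dbeta * st$u + beta * dst$u + (1 - beta) * lay$R * dbsum -
          dbeta * lay$R * bsum - dst$o * lay$u_th,
        hard = dbeta * (1 - st$o) * st$u + beta * (1 - st$o) * dst$u -
          beta * st$u * dst$o + (1 - beta) * lay$R * dbsum - dbeta * lay$R * bsum,
        none = dbeta * st$u + beta * dst$u + (1 - beta) * lay$R * dbsum -
          dbeta * lay$R * bsum
      )
      o_new <- fire(u_new, lay$u_th)
      do_new <- surrogate_derivative(u_new, lay$u_th, sp) * du_new
      states[[l]] <- structure(list(u = u_new, i = i_new, o = o_new),
                               class = "layer_state")
      dstates[[l]] <- structure(list(u = du_new, i = di_new, o = do_new),
                                class = "layer_state")
      inp <- o_new; dinp <- do_new
    }
    o_last[t, ] <- states[[L]]$o
    do_last[t, ] <- dstates[[L]]$o
  }

  ro <- model$readout
  tro <- tv$readout
  n_mask <- sum(mask)
  dL <- 0
  for (t in which(mask)) {
    z <- as.numeric(ro$W %*% o_last[t, ] + ro$b)
    dz <- as.numeric(tro$W %*% o_last[t, ] + ro$W %*% do_last[t, ] + tro$b)
    p <- softmax_vec(z)
    y <- numeric(length(z)); y[labels[t] + 1L] <- 1
    dL <- dL + sum((p - y) * dz) / n_mask
  }
  dL
}

# a copy of the model with all parameters zeroed (tangent container)
new_zero_model <- function(model) {
  unflatten_params(model, numeric(length(flatten_params(model))))
}

#' Check analytic BPTT gradients against independent oracles
#'
#' Two routes:
#' \describe{
#'   \item{finite differences}{central differences of a scalar loss through
#'     the actual forward pass, compared parameter-by-parameter against the
#'     reverse-mode gradients. Meaningful in the sub-threshold regime (no
#'     spikes, narrow surrogate), where the trajectory is a smooth linear
#'     system; the quadratic membrane loss `0.5 * sum(u_T^2)` on the final
#'     step is used so hidden weights receive gradient without any spiking.}
#'   \item{forward mode}{directional derivatives of the masked cross-entropy,
#'     propagated through the straight-through surrogate graph, compared with
#'     the inner product of the reverse-mode gradient and the same random
#'     directions. Valid in the spiking regime; reverse and forward mode
#'     differentiate the identical computation and must agree to float
#'     precision.}
#' }
#'
#' @param model a small `dh_model` (a few dozen parameters keeps FD fast).
#' @param sample an `xor_sample` (its labels/mask drive the CE route).
#' @param tolerance reporting threshold for the FD route.
#' @param fd_eps central-difference step.
#' @param n_directions number of random tangents for the forward-mode route.
#' @return a `gradcheck_report`: max relative errors per route, per-group FD
#'   errors, spike count of the trajectory, and a `pass` flag. Non-finite
#'   gradients fail the check outright.
#' @export
gradcheck <- function(model, sample, tolerance = 1e-4, fd_eps = 1e-5,
                      n_directions = 5) {
  x <- as_matrix(sample$spikes)
  labels <- sample$labels
  mask <- sample$decision_mask
  fwd <- forward(model, x, record = TRUE)
  n_spikes <- sum(vapply(fwd$spikes, sum, numeric(1)))
  L <- length(model$layers)

  # ---- FD route: quadratic loss on the final membrane potentials ----
  quad_loss <- function(m) {
    f <- forward(m, x, record = TRUE)
    0.5 * sum(f$record[[length(m$layers)]]$u[nrow(x), ]^2)
  }
  inject <- lapply(model$layers, function(l) matrix(0, nrow(x), l$n))
  inject[[L]][nrow(x), ] <- fwd$record[[L]]$u[nrow(x), ]
  bw_quad <- dh_backward(model, x, fwd = fwd, inject_u = inject)
  g_quad <- flatten_grads(model, bw_quad$grads)
  theta <- flatten_params(model)
  g_fd <- vapply(seq_along(theta), function(j) {
    tp <- theta; tp[j] <- tp[j] + fd_eps
    tm <- theta; tm[j] <- tm[j] - fd_eps
    (quad_loss(unflatten_params(model, tp)) -
       quad_loss(unflatten_params(model, tm))) / (2 * fd_eps)
  }, numeric(1))
  # readout parameters do not touch the membrane loss; compare the rest
  groups <- param_groups(model)
  state_params <- !grepl("^readout", groups)
  denom <- pmax(abs(g_fd), abs(g_quad), 1e-8)
  rel <- abs(g_fd - g_quad) / denom
  fd_max <- max(rel[state_params])
  fd_by_group <- tapply(rel[state_params], groups[state_params], max)

  # ---- forward-mode route: masked CE through the spiking trajectory ----
  bw_ce <- dh_backward(model, x, labels = labels, mask = mask, fwd = fwd)
  g_ce <- flatten_grads(model, bw_ce$grads)
  tangent_err <- vapply(seq_len(n_directions), function(k) {
    v <- stats::rnorm(length(theta))
    v <- v / sqrt(sum(v^2))
    dl_fwd <- loss_tangent(model, x, labels, mask, v)
    dl_rev <- sum(g_ce * v)
    abs(dl_fwd - dl_rev) / max(abs(dl_fwd), abs(dl_rev), 1e-10)
  }, numeric(1))
  finite <- all(is.finite(g_quad)) && all(is.finite(g_ce)) &&
    all(is.finite(tangent_err))

  structure(list(
    fd_max_rel_err = fd_max,
    fd_by_group = fd_by_group,
    tangent_max_rel_err = max(tangent_err),
    n_params = length(theta),
    n_spikes = n_spikes,
    finite = finite,
    # FD is only probative when the trajectory is spike-free (smooth regime)
    pass = finite && max(tangent_err) < 1e-6 &&
      (n_spikes > 0 || fd_max < tolerance)
  ), class = "gradcheck_report")
}

#' @export
print.gradcheck_report <- function(x, ...) {
  cat(sprintf(
    paste0("<gradcheck> %d params, %d spikes | FD max rel err %.3g | ",
           "forward-mode max rel err %.3g | %s\n"),
    x$n_params, x$n_spikes, x$fd_max_rel_err, x$tangent_max_rel_err,
    if (x$pass) "PASS" else "FAIL"
  ))
  invisible(x)
}
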