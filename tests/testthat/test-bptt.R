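test_that("adjoints are zero with no loss and saturated branches stop weight flow", {
  m <- tiny_model()
  s <- tiny_sample()
  # no labels, no injections: nothing to propagate
  bw <- dh_backward(m, s$spikes)
  g <- dhsnn:::flatten_grads(m, bw$grads)
  expect_equal(g, numeric(length(g)))
  # alpha = 1 exactly: the (1 - alpha) factor kills all weight gradients
  m1 <- tiny_model(branches = 1)
  m1$layers[[1]]$alpha_fixed <- matrix(1, 1, m1$layers[[1]]$n)
  m1$layers[[1]]$alpha_learnable <- FALSE
  bw1 <- dh_backward(m1, s$spikes, labels = s$labels, mask = s$decision_mask)
  for (d in seq_along(bw1$grads$layers[[1]]$W)) {
    expect_equal(max(abs(bw1$grads$layers[[1]]$W[[d]])), 0)
    expect_equal(max(abs(bw1$grads$layers[[1]]$U[[d]])), 0)
  }
})

test_that("sub-threshold gradients match central finite differences", {
  m <- subthreshold_model()
  s <- tiny_sample()
  fwd <- forward(m, s$spikes)
  expect_equal(sum(vapply(fwd$spikes, sum, numeric(1))), 0)  # truly spike-free
  rep <- withr::with_seed(4, gradcheck(m, s, tolerance = 1e-4))
  expect_true(rep$finite)
  expect_lt(rep$fd_max_rel_err, 1e-4)
  expect_true(rep$pass)
})

test_that("reverse mode equals forward mode through the spiking graph", {
  for (seed in 1:3) {
    m <- tiny_model(seed = seed, branches = 2, recurrent = TRUE)
    s <- tiny_sample(seed = seed)
    fwd <- forward(m, s$spikes)
    rep <- withr::with_seed(seed, gradcheck(m, s))
    expect_true(rep$finite)
    expect_lt(rep$tangent_max_rel_err, 1e-9)
  }
})

test_that("gradcheck is deterministic under a fixed seed", {
  m <- tiny_model()
  s <- tiny_sample()
  r1 <- withr::with_seed(9, gradcheck(m, s))
  r2 <- withr::with_seed(9, gradcheck(m, s))
  expect_identical(r1, r2)
})

test_that("compiled batched backward equals the plain-R reference", {
  for (cfg in list(list(branches = 1, recurrent = FALSE),
                   list(branches = 2, recurrent = TRUE))) {
    m <- tiny_model(n_inputs = 6, layers = c(5, 4), branches = cfg$branches,
                    recurrent = cfg$recurrent, seed = 31)
    s <- withr::with_seed(13, multiscale_xor_sample(
      params = task_params(n_channels = 3)))
    bwR <- dh_backward(m, s$spikes, labels = s$labels, mask = s$decision_mask)
    res <- dhsnn:::run_batch(m, list(s), grad = TRUE)
    expect_equal(res$loss, bwR$loss, tolerance = 1e-12)
    gR <- dhsnn:::flatten_grads(m, bwR$grads)
    gC <- dhsnn:::flatten_grads(m, res$grads)
    expect_lt(max(abs(gR - gC)), 1e-12 * max(1, max(abs(gR))))
  }
})

test_that("gradients never leak outside the branch supports", {
  m <- tiny_model(n_inputs = 8, layers = 6, branches = 2, recurrent = TRUE,
                  seed = 5)
  s <- withr::with_seed(2, multiscale_xor_sample(
    params = task_params(n_channels = 4)))
  bw <- dh_backward(m, s$spikes, labels = s$labels, mask = s$decision_mask)
  lay <- m$layers[[1]]
  for (d in seq_len(lay$d)) {
    off <- lay$mask_W[[d]] == 0
    expect_true(all(bw$grads$layers[[1]]$W[[d]][off] == 0))
    off_u <- lay$mask_U[[d]] == 0
    expect_true(all(bw$grads$layers[[1]]$U[[d]][off_u] == 0))
  }
})

test_that("the degenerate one-branch zero-alpha network has vanilla gradients", {
  set.seed(77)
  n <- 3; mch <- 4
  W <- matrix(runif(n * mch, -1.5, 1.5), n, mch)
  U <- matrix(runif(n * n, -0.8, 0.8), n, n)
  beta_raw <- rnorm(n)
  Wro <- matrix(runif(2 * n, -1, 1), 2, n); bro <- c(0.1, -0.1)
  lay <- dh_layer(n = n, m = mch, d = 1, W = list(W), U = list(U),
                  alpha_fixed = matrix(0, 1, n), beta_raw = beta_raw,
                  u_th = 0.3)
  model <- dh_model(list(lay), list(kind = "linear_per_step", W = Wro, b = bro))
  s <- tiny_sample(n_channels = 4, seed = 3)
  fwd <- forward(model, s$spikes, record = TRUE)
  expect_gt(sum(fwd$spikes[[1]]), 0)      # comparison exercises spikes/resets
  ref <- vanilla_soft_reference(W, U, beta_raw, 0.3, Wro, bro,
                                s$spikes, s$labels, s$decision_mask,
                                model$config$surrogate)
  expect_equal(fwd$record[[1]]$u, ref$u, tolerance = 1e-6)
  expect_equal(fwd$spikes[[1]], ref$o)
  bw <- dh_backward(model, s$spikes, labels = s$labels, mask = s$decision_mask,
                    fwd = fwd)
  expect_equal(bw$loss, ref$loss, tolerance = 1e-10)
  expect_equal(bw$grads$layers[[1]]$W[[1]], ref$grads$W, tolerance = 1e-10)
  expect_equal(bw$grads$layers[[1]]$U[[1]], ref$grads$U, tolerance = 1e-10)
  expect_equal(bw$grads$layers[[1]]$beta_raw, ref$grads$beta_raw,
               tolerance = 1e-10)
  expect_equal(bw$grads$readout$W, ref$grads$Wro, tolerance = 1e-10)
  expect_equal(bw$grads$readout$b, ref$grads$bro, tolerance = 1e-10)
})

test_that("adjoint traces expose reset-driven decay vs dendritic persistence", {
  params <- task_params(n_channels = 5, delay_ms = 30)
  s <- withr::with_seed(6, delayed_xor_sample(params = params))
  dh <- build_network(network_config(n_inputs = 5, n_classes = 2,
                                     layer_sizes = 16, branches = 1,
                                     init_alpha = "large", seed = 2))
  van <- build_network(network_config(n_inputs = 5, n_classes = 2,
                                      layer_sizes = 16, branches = 1,
                                      alpha_fixed = 0, init_beta = "large",
                                      seed = 2))
  tr_dh <- gradient_trace(dh, s)
  tr_v <- gradient_trace(van, s)
  t_loss <- max(which(s$decision_mask))
  expect_length(tr_dh[[1]]$di, nrow(s$spikes))
  # dendritic adjoints reach the first step far better than vanilla membranes
  expect_gt(tr_dh[[1]]$di[1] / tr_dh[[1]]$di[t_loss],
            tr_v[[1]]$du[1] / tr_v[[1]]$du[t_loss])
})
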