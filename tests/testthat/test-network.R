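test_that("building is deterministic and weight counts do not grow with branches", {
  cfg <- function(D) network_config(n_inputs = 12, n_classes = 2,
                                    layer_sizes = 8, branches = D, seed = 21)
  m1 <- build_network(cfg(2))
  m2 <- build_network(cfg(2))
  expect_identical(flatten_params(m1), flatten_params(m2))
  expect_identical(m1$partitions[[1]]$ff$P, m2$partitions[[1]]$ff$P)
  weights <- vapply(c(1, 2, 4, 8), function(D) {
    count_params(build_network(cfg(D)), breakdown = TRUE)$weights
  }, numeric(1))
  expect_equal(weights, rep(8 * 12, 4))
  # total parameters grow only by the N x D dendritic scalars
  t1 <- count_params(build_network(cfg(1)), breakdown = TRUE)
  t4 <- count_params(build_network(cfg(4)), breakdown = TRUE)
  expect_equal(t4$timing - t1$timing, 8 * (4 - 1))
})

test_that("a vanilla network is the frozen-zero-alpha special case", {
  cfg <- network_config(n_inputs = 6, n_classes = 2, layer_sizes = 5,
                        branches = 1, alpha_fixed = 0, seed = 3)
  m <- build_network(cfg)
  expect_false(m$layers[[1]]$alpha_learnable)
  expect_equal(layer_alpha(m$layers[[1]]), matrix(0, 1, 5))
  # its parameter count differs from the DH twin by exactly N x D alphas
  cfg_dh <- network_config(n_inputs = 6, n_classes = 2, layer_sizes = 5,
                           branches = 1, seed = 3)
  diff <- count_params(build_network(cfg_dh)) - count_params(m)
  expect_equal(diff, 5L)
})

test_that("forward is quiescent on silence and recurrence is inert at T = 1", {
  m <- tiny_model(n_inputs = 4, layers = c(5, 4), branches = 2,
                  recurrent = TRUE, seed = 6)
  zero <- matrix(0, 20, 4)
  fwd <- forward(m, zero)
  expect_true(all(vapply(fwd$spikes, function(o) all(o == 0), logical(1))))
  # at T = 1 the one-step-delayed recurrent term cannot contribute
  x1 <- matrix(1, 1, 4)
  m_blown <- m
  for (d in 1:2) m_blown$layers[[1]]$U[[d]] <- m$layers[[1]]$U[[d]] * 1e6
  expect_equal(forward(m, x1)$spikes, forward(m_blown, x1)$spikes)
  # recurrent layer with U = 0 behaves exactly like the feedforward twin
  m_zeroU <- m
  for (d in 1:2) m_zeroU$layers[[1]]$U[[d]] <- m$layers[[1]]$U[[d]] * 0
  m_ff <- m
  m_ff$layers[[1]]$U <- NULL
  m_ff$layers[[1]]$mask_U <- NULL
  x <- unclass(random_spikes(25, 4, seed = 4))
  expect_equal(forward(m_zeroU, x)$spikes, forward(m_ff, x)$spikes)
})

test_that("readout variants decode spikes as specified", {
  m <- tiny_model(n_inputs = 3, layers = 4, recurrent = FALSE, seed = 2)
  # silent last layer + zero bias: uniform probabilities, loss log(K)
  o <- matrix(0, 6, 4)
  m$readout$b <- c(0, 0)
  r <- readout(m, o, labels = rep(0L, 6), mask = rep(TRUE, 6))
  expect_equal(unname(r$scores), matrix(0.5, 6, 2))
  expect_equal(r$loss, log(2), tolerance = 1e-12)

  # spike_count: the class whose output neuron fires every step wins
  msc <- m
  msc$readout <- list(kind = "spike_count", W = diag(2)[, c(1, 2, 1, 2)] * 0,
                      b = c(0, 0), beta_raw = c(0, 0))
  msc$readout$W <- matrix(0, 2, 4); msc$readout$W[2, ] <- 5
  o_fire <- matrix(1, 6, 4)
  rsc <- readout(msc, o_fire)
  expect_gt(rsc$scores[2], rsc$scores[1])

  # leaky decode orders: per-step softmax then average vs softmax of the sum
  mlk <- m
  mlk$readout <- list(kind = "leaky_sum_softmax", W = rbind(c(2, 0, 0, 0),
                                                            c(0, 1, 0, 0)),
                      b = c(0, 0), beta_raw = c(-40, -40))  # beta ~ 0
  o2 <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))    # drive (2,0) then (0,1)
  p_sum_soft <- readout(mlk, o2)$scores
  mlk$readout$kind <- "leaky_softmax_sum"
  p_soft_sum <- readout(mlk, o2)$scores
  exp_sum_soft <- (c(exp(2), 1) / (exp(2) + 1) + c(1, exp(1)) / (1 + exp(1))) / 2
  exp_soft_sum <- c(exp(2), exp(1)) / (exp(2) + exp(1))
  expect_equal(as.numeric(p_sum_soft), exp_sum_soft, tolerance = 1e-6)
  expect_equal(as.numeric(p_soft_sum), exp_soft_sum, tolerance = 1e-6)
  expect_false(isTRUE(all.equal(p_sum_soft, p_soft_sum)))
})

test_that("masked cross-entropy ignores unmasked steps", {
  scores <- rbind(c(1, 0), c(0.5, 0.5), c(0.001, 0.999))
  labels <- c(0L, 1L, 1L)
  expect_equal(masked_loss(scores, labels, c(TRUE, TRUE, TRUE)),
               mean(-log(c(1, 0.5, 0.999))))
  expect_equal(masked_loss(scores, labels, c(TRUE, FALSE, FALSE)), 0)
  expect_equal(masked_loss(scores, labels, c(FALSE, FALSE, TRUE)),
               -log(0.999))
  expect_error(masked_loss(scores, labels, c(FALSE, FALSE, FALSE)), "empty")
})

test_that("a saved model reloads to bitwise-identical behaviour", {
  m <- tiny_model(seed = 14)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  x <- unclass(random_spikes(15, 3, seed = 5))
  expect_identical(forward(m, x), forward(m2, x))
  expect_identical(flatten_params(m), flatten_params(m2))
})

test_that("YAML configs map onto network_config and reject unknown keys", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_inputs: 40", "n_classes: 2", "layer_sizes: [64, 64]",
               "branches: 1", "init_alpha: large", "seed: 4"), path)
  cfg <- read_config_yaml(path)
  expect_s3_class(cfg, "network_config")
  expect_equal(cfg$layer_sizes, c(64L, 64L))
  writeLines(c("n_inputs: 4", "n_classes: 2", "bogus_knob: 1"), path)
  expect_error(read_config_yaml(path), "bogus_knob")
})
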