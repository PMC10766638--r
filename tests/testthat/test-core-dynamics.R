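test_that("timing-factor clamp is the logistic and stays inside (0,1)", {
  expect_identical(clamp_timing(0), 0.5)
  expect_lt(clamp_timing(20), 1)
  expect_lt(abs(clamp_timing(20) - 1), 1e-8)
  expect_equal(clamp_timing(log(9)), 0.9, tolerance = 1e-12)
  # strictly inside (0,1) up to where double precision can resolve the gap
  raw <- withr::with_seed(1, runif(500, -34, 34))
  v <- clamp_timing(raw)
  expect_true(all(v > 0 & v < 1))
  expect_true(all(diff(clamp_timing(sort(raw))) >= 0))
  expect_equal(unclamp_timing(clamp_timing(2.5)), 2.5, tolerance = 1e-10)
})

test_that("dendritic currents interpolate between memoryless and perfect memory", {
  expect_equal(dendrite_step(5, 0, 2), 2)
  expect_equal(dendrite_step(3, 1, 99), 3)
  # zero input for k steps multiplies the current by alpha^k exactly
  i <- 1
  for (k in 1:7) i <- dendrite_step(i, 0.9, 0)
  expect_equal(i, 0.9^7, tolerance = 1e-12)
  expect_error(dendrite_step(c(1, 2), 0.5, c(1, 2, 3)), "shapes")
  expect_error(dendrite_step(c(1, 2, 3), c(0.5, 0.5), c(1, 2, 3)), "broadcast")
})

test_that("soma update applies leak, input scaling and previous-spike soft reset", {
  expect_equal(soma_step(1, 0.5, 0, o_prev = 1, u_th = 0.5), 0)
  expect_equal(soma_step(7, 0, 2, o_prev = 0, u_th = 0.3, R = 1), 2)
  expect_equal(soma_step(0, 0.8, 1, o_prev = 0, u_th = 0.3, R = 1), 0.2,
               tolerance = 1e-12)
})

test_that("spike emission is Heaviside with H(0) = 1", {
  expect_equal(fire(0.3, 0.3), 1)
  expect_equal(fire(0.3 - 1e-9, 0.3), 0)
  expect_equal(fire(c(-1, 0.3, 2), 0.3), c(0, 1, 1))
})

test_that("quiescence is a fixed point and the reset uses the previous spike", {
  m <- tiny_model(recurrent = FALSE)
  st <- new_layer_state(m$layers[[1]]$n, m$layers[[1]]$d)
  st2 <- layer_step(st, m$layers[[1]], numeric(3))
  expect_equal(st2$u, numeric(4))
  expect_equal(as.numeric(st2$i), numeric(8))
  expect_equal(st2$o, numeric(4))

  # single neuron, instantaneous branch: threshold crossing at t must NOT be
  # reduced by the same step's own spike; the subtraction lands at t + 1
  lay <- dh_layer(n = 1, m = 1, d = 1, W = list(matrix(1, 1, 1)),
                  alpha_fixed = matrix(0, 1, 1), beta_fixed = 0, u_th = 0.3)
  s0 <- new_layer_state(1, 1)
  s1 <- layer_step(s0, lay, 1)       # u = 1 >= 0.3, fires, no same-step reset
  expect_equal(s1$u, 1)
  expect_equal(s1$o, 1)
  s2 <- layer_step(s1, lay, 0)       # now the reset for s1's spike applies
  expect_equal(s2$u, -0.3)
  expect_error(layer_step(s1, lay, c(1, 1)), "fan-in")
})

test_that("one zero-alpha branch degenerates to the vanilla soft-reset LIF", {
  set.seed(42)
  n <- 3; mch <- 4; T_len <- 50
  W <- matrix(runif(n * mch, -1, 1), n, mch)
  U <- matrix(runif(n * n, -0.5, 0.5), n, n)
  beta_raw <- rnorm(n)
  lay <- dh_layer(n = n, m = mch, d = 1, W = list(W), U = list(U),
                  alpha_fixed = matrix(0, 1, n), beta_raw = beta_raw,
                  u_th = 0.3)
  x <- unclass(random_spikes(T_len, mch, seed = 9))
  st <- new_layer_state(n, 1)
  stv <- list(u = numeric(n), o = numeric(n))
  pv <- list(W = W, U = U, beta = clamp_timing(beta_raw), u_th = 0.3)
  for (t in seq_len(T_len)) {
    st <- layer_step(st, lay, x[t, ])
    stv <- vanilla_lif_step(stv, pv, x[t, ], reset_mode = "soft")
    expect_equal(st$u, stv$u, tolerance = 1e-6)
    expect_equal(st$o, stv$o)
  }
})

test_that("vanilla reset modes behave as hard-clear, soft-subtract, no-reset", {
  p <- list(W = matrix(2, 1, 1), beta = 0.6, u_th = 0.3)
  st <- list(u = 1.5, o = 1)
  expect_equal(vanilla_lif_step(st, p, 0, "hard")$u, 0)          # memory cleared
  expect_equal(vanilla_lif_step(st, p, 0, "soft")$u, 0.6 * 1.5 - 0.3)
  expect_equal(vanilla_lif_step(st, p, 0, "none")$u, 0.6 * 1.5)
  # without reset and zero drive the membrane decays exactly geometrically
  u <- 2; st <- list(u = u, o = 0)
  for (k in 1:6) st <- vanilla_lif_step(st, p, 0, "none")
  expect_equal(st$u, 2 * 0.6^6, tolerance = 1e-12)
  expect_error(vanilla_lif_step(st, p, 0, "bogus"))
})

test_that("two branches with different alphas separate slow and fast inputs", {
  # branch 1 (alpha .99) sees channel A, branch 2 (alpha .1) channel B
  W1 <- matrix(c(1, 0), 1, 2); W2 <- matrix(c(0, 1), 1, 2)
  lay <- dh_layer(n = 1, m = 2, d = 2, W = list(W1, W2),
                  alpha_fixed = matrix(c(0.99, 0.1), 2, 1),
                  beta_fixed = 0.5, u_th = 10)   # threshold high: no spikes
  st <- new_layer_state(1, 2)
  for (t in 1:5) st <- layer_step(st, lay, c(1, 0))   # burst on A
  i1_burst <- st$i[1, 1]
  for (k in 1:10) st <- layer_step(st, lay, c(0, 0))  # silence
  expect_equal(st$i[1, 1], i1_burst * 0.99^10, tolerance = 1e-10)
  expect_lt(st$i[2, 1], 1e-9)         # fast branch has forgotten everything
  # fast branch tracks B almost instantly
  st <- layer_step(st, lay, c(0, 1))
  expect_gt(st$i[2, 1], 0.89)        # (1 - alpha) * 1 = 0.9 within one step
  expect_lt(abs(st$i[1, 1] - i1_burst * 0.99^11), 1e-10)
})

test_that("dendritic persistence holds along whole random trajectories", {
  m <- tiny_model(recurrent = FALSE, branches = 2, seed = 8)
  x <- unclass(random_spikes(30, 3, seed = 2))
  x[11:30, ] <- 0                     # silence after step 10
  fwd <- forward(m, x, record = TRUE)
  alpha <- layer_alpha(m$layers[[1]])
  i10 <- fwd$record[[1]]$i[10, , ]
  i30 <- fwd$record[[1]]$i[30, , ]
  expect_equal(i30, i10 * alpha^20, tolerance = 1e-8)
})
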