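test_that("Bernoulli patterns have the configured firing statistics", {
  params <- task_params()
  counts <- withr::with_seed(1, {
    vapply(1:4000, function(i) sum(gen_pattern("high", params)), numeric(1))
  })
  n_bins <- params$pattern_steps * params$n_channels    # 10 x 20
  se <- sqrt(n_bins * 0.6 * 0.4 / 4000)
  expect_lt(abs(mean(counts) - n_bins * 0.6), 3 * se)
  counts_low <- withr::with_seed(2, {
    vapply(1:4000, function(i) sum(gen_pattern("low", params)), numeric(1))
  })
  se_low <- sqrt(n_bins * 0.2 * 0.8 / 4000)
  expect_lt(abs(mean(counts_low) - n_bins * 0.2), 3 * se_low)
  expect_gt(mean(counts), mean(counts_low))
  # a count threshold at 10 * C * 0.4 separates low from high patterns
  thr <- n_bins * 0.4
  expect_gt(mean(counts > thr), 0.999)
  expect_gt(mean(counts_low < thr), 0.999)
  expect_identical(withr::with_seed(3, unclass(gen_pattern("high", params))),
                   withr::with_seed(3, unclass(gen_pattern("high", params))))
})

test_that("delayed XOR samples have the stated layout and truth table", {
  params <- task_params(delay_ms = 50)
  s <- withr::with_seed(4, delayed_xor_sample(params = params))
  expect_equal(nrow(s$spikes), 2 * 10 + 50 + 10)
  expect_equal(ncol(s$spikes), 20)
  expect_true(all(unclass(s$spikes) %in% c(0, 1)))
  expect_equal(which(s$decision_mask), 71:80)
  # forced rate combinations follow XOR semantics
  for (combo in list(c("low", "low", 0), c("low", "high", 1),
                     c("high", "low", 1), c("high", "high", 0))) {
    s2 <- delayed_xor_sample(params = params, rates = combo[1:2])
    expect_equal(s2$decision_labels, as.integer(combo[3]))
  }
  # zero delay degenerates to back-to-back patterns but stays well formed
  s0 <- delayed_xor_sample(delay_ms = 0, params = params)
  expect_equal(nrow(s0$spikes), 30)
  expect_equal(sum(s0$decision_mask), 10)
})

test_that("multi-timescale XOR emits one decision per fast pattern", {
  params <- task_params()
  s <- withr::with_seed(5, multiscale_xor_sample(params = params))
  expect_equal(nrow(s$spikes), 10 + 4 * (10 + 5))
  expect_equal(ncol(s$spikes), 40)
  expect_equal(max(s$decision_id), 4L)
  s3 <- multiscale_xor_sample(
    n_repeats = 3, params = params,
    rates = list(s1 = "high", s2 = c("high", "low", "high")))
  expect_equal(s3$decision_labels, c(0L, 1L, 0L))
  s1 <- multiscale_xor_sample(n_repeats = 1, params = params)
  expect_equal(max(s1$decision_id), 1L)
  expect_equal(nrow(s1$spikes), 10 + 15)
})

test_that("labels always recompute from the hidden rates and stay balanced", {
  params <- task_params()
  samples <- withr::with_seed(6, xor_dataset(300, "multiscale", params))
  labs <- unlist(lapply(samples, function(s) {
    expected <- unname(vapply(s$meta$rates$s2, function(r2) {
      as.integer(xor(s$meta$rates$s1 == "high", r2 == "high"))
    }, integer(1)))
    expect_equal(s$decision_labels, expected)
    expect_equal(unique(stats::na.omit(s$labels[s$decision_mask])),
                 unique(s$decision_labels[s$decision_id[s$decision_mask]]))
    s$decision_labels
  }))
  # 1200 Bernoulli(1/2) decisions: 3 sigma is ~4.3 points
  expect_lt(abs(mean(labs) - 0.5), 3 * sqrt(0.25 / length(labs)))
})

test_that("Poisson noise only ever adds spikes, at the requested rate", {
  clean <- random_spikes(50, 10, p = 0.2, seed = 7)
  expect_identical(inject_poisson_noise(clean, 0), clean)
  noisy <- withr::with_seed(8, inject_poisson_noise(clean, 100))
  expect_true(all(unclass(noisy) >= unclass(clean)))
  # empirical rate on an empty train: 100 Hz at dt = 1 ms is p = 0.1 per bin
  zero <- spike_train(matrix(0, 1000, 100))
  z <- withr::with_seed(9, inject_poisson_noise(zero, 100))
  p_hat <- mean(unclass(z))
  expect_lt(abs(p_hat - 0.1), 3 * sqrt(0.1 * 0.9 / 1e5))
})

test_that("the bursting demo drive has two well-separated timescales", {
  params <- task_params(n_channels = 4)
  drive <- bursting_demo_inputs(params, T_steps = 200, drive_period = 3,
                                modulator_period = 100)
  expect_equal(dim(unclass(drive)), c(200L, 8L))
  fast <- unclass(drive)[, 1:4]
  slow <- unclass(drive)[, 5:8]
  expect_equal(which(fast[, 1] == 1), seq(3, 200, by = 3))
  expect_equal(slow[1:50, 1], rep(1, 50))      # "on" half of the cycle
  expect_equal(slow[51:100, 1], rep(0, 50))
  # a fast branch driven by the periodic block fires near the drive period
  lay <- dh_layer(n = 1, m = 8, d = 2,
                  W = list(cbind(matrix(0.5, 1, 4), matrix(0, 1, 4)),
                           cbind(matrix(0, 1, 4), matrix(0.2, 1, 4))),
                  alpha_fixed = matrix(c(0.1, 0.99), 2, 1),
                  beta_fixed = 0.3, u_th = 0.5)
  silenced <- unclass(drive)
  silenced[, 5:8] <- 0
  st <- new_layer_state(1, 2)
  spikes <- vapply(seq_len(200), function(t) {
    st <<- layer_step(st, lay, silenced[t, ])
    st$o
  }, numeric(1))
  expect_gt(sum(spikes), 200 / 3 * 0.5)
  expect_lt(sum(spikes), 200 / 3 * 1.5)
})

test_that("samples round-trip through the sparse units/times JSON layout", {
  params <- task_params(n_channels = 5)
  samples <- withr::with_seed(10, xor_dataset(3, "multiscale", params))
  path <- withr::local_tempfile(fileext = ".json")
  export_samples_json(samples, path)
  back <- import_samples_json(path)
  expect_length(back, 3)
  for (k in 1:3) {
    expect_equal(unclass(back[[k]]$spikes), unname(unclass(samples[[k]]$spikes)))
    expect_equal(back[[k]]$labels, samples[[k]]$labels)
    expect_equal(back[[k]]$decision_id, samples[[k]]$decision_id)
    expect_equal(back[[k]]$decision_labels, samples[[k]]$decision_labels)
  }
})
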