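test_that("filter configuration wires taps and delays correctly", {
  cfg <- adaptive_filter_config("sensorimotor")
  state <- adaptive_filter_state(cfg, 200)
  expect_length(state$weights, 200L)
  expect_length(adaptive_filter_state(adaptive_filter_config("motor"),
                                      200)$weights, 100L)
  # tap spacing must land on the sample grid
  expect_error(adaptive_filter_state(
    adaptive_filter_config("motor", tap_spacing_s = 0.003), 200),
    "whole number of samples")
})

test_that("component assembly reflects the configured delay lines", {
  cfg <- adaptive_filter_config("motor", n_taps_per_input = 5,
                                processing_delay_s = 0.01)
  state <- adaptive_filter_state(cfg, 200)
  # no samples pushed: components are all zero
  first <- assemble_components(state, 1, 0)
  expect_identical(first$p, numeric(5))
  # constant input: once buffers fill, every tap sees the constant
  state <- first$state
  for (i in 1:20) state <- assemble_components(state, 1, 0)$state
  expect_identical(assemble_components(state, 1, 0)$p, rep(1, 5))

  # sensorimotor concatenates motor then delayed-sensory blocks
  cfg2 <- adaptive_filter_config("sensorimotor", n_taps_per_input = 3,
                                 processing_delay_s = 0.005,
                                 sensory_decorrelation_delay_s = 0.01)
  st <- adaptive_filter_state(cfg2, 200)
  seqs <- seq_len(12)
  for (i in seqs) {
    out <- assemble_components(st, i, 100 + i)
    st <- out$state
  }
  # at t = 12: motor delayed 1 sample, taps at lags 1,2,3;
  # sensory delayed 1 + 2 samples, taps at lags 3,4,5
  expect_identical(out$p, c(11, 10, 9, 109, 108, 107))
})

test_that("prediction is the weight-component inner product", {
  cfg <- adaptive_filter_config("motor", n_taps_per_input = 5,
                                processing_delay_s = 0)
  state <- adaptive_filter_state(cfg, 200)
  expect_identical(filter_predict(state, rep(3, 5)), 0)
  w <- withr::with_seed(1, rnorm(5))
  p <- withr::with_seed(2, rnorm(5))
  state$weights <- w
  brute <- 0
  for (i in 1:5) brute <- brute + w[i] * p[i]
  expect_equal(filter_predict(state, p), brute, tolerance = 1e-15)
  # selector weight reads out a delayed input sample
  state$weights <- c(0, 0, 1, 0, 0)
  for (i in 1:9) state <- assemble_components(state, i, 0)$state
  out <- assemble_components(state, 10, 0)
  expect_identical(filter_predict(out$state, out$p), 8)  # lag 2 at delay 0
  expect_error(filter_predict(state, rep(1, 4)), "length")
})

test_that("LMS updates follow w <- w + beta p e and stop on divergence", {
  cfg <- adaptive_filter_config("motor", n_taps_per_input = 4,
                                learning_rate = 0.1)
  state <- adaptive_filter_state(cfg, 200)
  state$weights <- rep(1, 4)
  p <- c(1, 2, 3, 4)
  expect_identical(lms_update(state, p, 0)$weights, rep(1, 4))
  expect_identical(lms_update(state, numeric(4), 5)$weights, rep(1, 4))
  expect_equal(lms_update(state, p, 2)$weights, 1 + 0.1 * p * 2,
               tolerance = 1e-15)
  expect_error(lms_update(state, p, NaN), "diverged")
})

test_that("step-wise R path agrees with the compiled whole-record path", {
  fs <- 200
  n <- 300
  u <- make_bandpass_noise(2, 4, n / fs, fs, seed = 31)
  z <- whisk_ts(0.8 * u$values + withr::with_seed(32, rnorm(n, sd = 0.1)),
                fs)
  for (mode in c("motor", "sensory", "sensorimotor")) {
    cfg <- adaptive_filter_config(mode, n_taps_per_input = 8,
                                  learning_rate = 0.01,
                                  sensory_decorrelation_delay_s = 0.05)
    run <- run_novelty_scheme(u, z, cfg, snapshot_every_s = 0)
    state <- adaptive_filter_state(cfg, fs)
    e_ref <- numeric(n)
    for (t in seq_len(n)) {
      out <- assemble_components(state, u$values[t], z$values[t])
      state <- out$state
      yhat <- filter_predict(state, out$p)
      e_ref[t] <- z$values[t] - yhat
      state <- lms_update(state, out$p, e_ref[t])
    }
    expect_equal(run$e$values, e_ref, tolerance = 1e-10)
    expect_equal(run$weights, state$weights, tolerance = 1e-10)
  }
})

test_that("an inert filter passes the raw signal through unchanged", {
  trial <- test_trial(duration_s = 20, seed = 41)
  cfg <- adaptive_filter_config("sensorimotor", learning_rate = 0)
  run <- run_novelty_scheme(trial$u, trial$z, cfg)
  expect_identical(run$e$values, trial$z$values)
  expect_identical(run$yhat$values, numeric(length(trial$z$values)))
})

test_that("motor-input LMS cancels a linear reafferent path", {
  fs <- 200
  u <- make_bandpass_noise(2, 4, 300, fs, seed = 51)
  r <- simulate_reafferent(test_plant(fs), u)
  cfg <- adaptive_filter_config("motor")
  run <- run_novelty_scheme(u, r, cfg, snapshot_every_s = 0)
  final <- (240 * fs):(300 * fs - 1)
  expect_lt(var(run$e$values[final]) / var(r$values[final]), 0.05)
  # converged prediction tracks the true reafference
  expect_gt(cor(run$yhat$values[final], r$values[final]), 0.99)
})

test_that("sensory-input LMS cancels a periodic signal from its own past", {
  fs <- 200
  u <- make_sine(3, sqrt(2), 300, fs)
  z <- simulate_reafferent(test_plant(fs), u)
  cfg <- adaptive_filter_config("sensory")
  run <- run_novelty_scheme(NULL, z, cfg, snapshot_every_s = 0)
  final <- (240 * fs):(300 * fs - 1)
  expect_lt(var(run$e$values[final]) / var(z$values[final]), 0.05)
})

test_that("frozen weights replay the prediction with no hidden state", {
  trial <- test_trial(duration_s = 60, seed = 61, drive = "stochastic")
  cfg <- adaptive_filter_config("sensorimotor")
  learn <- run_novelty_scheme(trial$u, trial$z, cfg, snapshot_every_s = 0)
  cfg0 <- cfg
  cfg0$learning_rate <- 0
  replay1 <- run_novelty_scheme(trial$u, trial$z, cfg0,
                                init_weights = learn$weights,
                                snapshot_every_s = 0)
  replay2 <- run_novelty_scheme(trial$u, trial$z, cfg0,
                                init_weights = learn$weights,
                                snapshot_every_s = 0)
  expect_identical(replay1$e$values, replay2$e$values)
  # pure prediction oracle at a handful of time points
  geom <- whisknovelty:::config_samples(cfg, 200)
  w <- learn$weights
  for (t in c(5000L, 8000L, 11000L)) {
    taps_u <- trial$u$values[t - geom$delay_m - (0:99) * geom$stride]
    taps_z <- trial$z$values[t - geom$delay_s - (0:99) * geom$stride]
    expect_equal(replay1$yhat$values[t],
                 sum(w * c(taps_u, taps_z)), tolerance = 1e-10)
  }
})

test_that("weights stay bounded under a safe learning rate", {
  trial <- test_trial(duration_s = 200, seed = 71, drive = "stochastic")
  cfg <- adaptive_filter_config("sensorimotor")
  # stability heuristic: beta < 2 / (taps x input power)
  power <- var(trial$z$values)
  expect_lt(cfg$learning_rate, 2 / (200 * power))
  run <- run_novelty_scheme(trial$u, trial$z, cfg, snapshot_every_s = 0)
  expect_true(all(is.finite(run$weights)))
  first <- 1:(40 * 200)
  final <- (160 * 200):(200 * 200 - 1)
  expect_lt(var(run$e$values[final]), var(run$e$values[first]))
})
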