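test_that("default plant is stable with unit DC gain", {
  p <- default_plant()
  expect_s3_class(p, "linear_plant")
  expect_equal(sum(p$b) / (1 + sum(p$a)), 1, tolerance = 1e-6)
  expect_lt(sqrt(abs(p$a[2])), 1)
  expect_error(linear_plant(c(-2, 1.1), c(1, 0)), "unstable")
})

test_that("reafferent simulation matches the transfer function", {
  p <- test_plant()
  fs <- p$sample_rate_hz
  zero <- whisk_ts(numeric(400), fs)
  expect_identical(simulate_reafferent(p, zero)$values, numeric(400))

  # impulse response against a polynomial long-division oracle
  imp <- whisk_ts(c(1, numeric(99)), fs)
  r <- simulate_reafferent(p, imp)$values
  h <- numeric(50)
  h[1] <- 0  # relative degree one: no instantaneous response
  h[2] <- p$b[1]
  h[3] <- p$b[2] - p$a[1] * h[2]
  for (t in 4:50) h[t] <- -p$a[1] * h[t - 1] - p$a[2] * h[t - 2]
  expect_equal(r[1:50], h, tolerance = 1e-12)
})

test_that("k = 0 bilinear path is bit-identical to a plain linear recursion", {
  p <- test_plant()
  u <- make_bandpass_noise(2, 4, 5, 200, seed = 11)
  r_cpp <- simulate_reafferent(bilinear_plant(p, 0), u)$values
  a1 <- p$a[1]; a2 <- p$a[2]; b1 <- p$b[1]; b2 <- p$b[2]
  uu <- u$values
  n <- length(uu)
  r_ref <- numeric(n)
  r_ref[2] <- -a1 * r_ref[1] + b1 * uu[1]
  for (t in 3:n) {
    r_ref[t] <- -a1 * r_ref[t - 1] - a2 * r_ref[t - 2] +
      b1 * uu[t - 1] + b2 * uu[t - 2]
  }
  expect_identical(r_cpp, r_ref)
})

test_that("bilinear simulation stays bounded on |u| <= 1 and guards blow-up", {
  p <- test_plant()
  bp <- bilinear_plant(p, 0.05)
  saw <- make_whisk_sawtooth(duration_s = 1000, sample_rate_hz = 200)
  expect_no_error(r1 <- simulate_reafferent(bp, saw))
  noise <- make_bandpass_noise(2, 4, 1000, 200, seed = 5)
  clipped <- whisk_ts(pmin(pmax(noise$values, -1), 1), 200)
  expect_no_error(r2 <- simulate_reafferent(bp, clipped))
  expect_true(all(is.finite(c(r1$values, r2$values))))

  # absurdly strong nonlinearity trips the divergence guard with an index
  wild <- bilinear_plant(p, 2)
  expect_error(simulate_reafferent(wild, make_sine(3, sqrt(2), 10, 200)),
               "diverged at sample")
  expect_error(simulate_reafferent(bp, whisk_ts(rep(1, 10), 100)), "rate")
})

test_that("contact schedules are Bernoulli draws per sample", {
  expect_length(generate_contact_schedule(10, 200, 1.0, seed = 1)$times, 0L)
  s1 <- generate_contact_schedule(100, 200, 0.999, seed = 2)
  s2 <- generate_contact_schedule(100, 200, 0.999, seed = 2)
  expect_identical(s1$times, s2$times)
  expect_true(all(diff(s1$times) > 0))
  expect_true(all(s1$times >= 1 & s1$times <= 20000))
  expect_error(generate_contact_schedule(10, 200, 1.5, seed = 1),
               "threshold")
})

test_that("exafferent rendering superposes impulse responses linearly", {
  fs <- 200
  h <- test_response(fs)
  len <- length(h$h)
  one <- contact_schedule_for_test(c(100L), fs)
  x1 <- render_exafferent(one, h, 400)
  expect_identical(x1$values[100:(99 + len)], h$h)
  expect_identical(x1$values[-(100:(99 + len))],
                   numeric(400 - len))

  # overlapping contacts add sample-wise
  two <- contact_schedule_for_test(c(100L, 110L), fs)
  x2 <- render_exafferent(two, h, 400)
  shifted <- numeric(400)
  shifted[100:(99 + len)] <- h$h
  shifted[110:(109 + len)] <- shifted[110:(109 + len)] + h$h
  expect_equal(x2$values, shifted, tolerance = 1e-15)

  # linearity over disjoint schedules
  sa <- contact_schedule_for_test(c(10L, 300L), fs)
  sb <- contact_schedule_for_test(c(150L, 420L), fs)
  sab <- contact_schedule_for_test(sort(c(sa$times, sb$times)), fs)
  expect_equal(render_exafferent(sab, h, 600)$values,
               render_exafferent(sa, h, 600)$values +
                 render_exafferent(sb, h, 600)$values,
               tolerance = 1e-15)
  expect_identical(render_exafferent(contact_schedule_for_test(integer(0), fs),
                                     h, 50)$values, numeric(50))
})

test_that("sensory composition is additive", {
  trial <- test_trial(duration_s = 30, seed = 3)
  expect_identical(compose_sensory(trial$r,
                                   whisk_ts(numeric(length(trial$r$values)),
                                            200))$values,
                   trial$r$values)
  expect_identical(trial$z$values, trial$r$values + trial$x$values)
  # uncorrelated components: variances add approximately
  long <- test_trial(duration_s = 1000, seed = 4, drive = "stochastic")
  vz <- var(long$z$values)
  expect_lt(abs(vz - var(long$r$values) - var(long$x$values)) / vz, 0.05)
})

test_that("least-squares identification recovers the plant", {
  p <- test_plant()
  u <- make_bandpass_noise(2, 4, 200, 200, seed = 6)
  r <- simulate_reafferent(p, u)
  fit <- identify_linear_plant(u, r)
  expect_lt(max(abs(c(fit$a - p$a, fit$b - p$b))), 1e-6)
  expect_lt(attr(fit, "residual_variance"), 1e-15)

  expect_error(identify_linear_plant(whisk_ts(rep(1, 5000), 200), r2 <-
                                       whisk_ts(rep(0.5, 5000), 200)),
               "ill-conditioned")

  # unmodelled nonlinearity inflates the linear fit's residual variance
  r_nl <- simulate_reafferent(bilinear_plant(p, 0.05), u)
  fit_nl <- identify_linear_plant(u, r_nl)
  expect_gt(attr(fit_nl, "residual_variance"),
            attr(fit, "residual_variance"))
})

test_that("contact responses are recoverable from prediction residuals", {
  fs <- 200
  trial <- test_trial(duration_s = 100, seed = 9, drive = "stochastic",
                      contact_threshold = 0.995)
  h_true <- test_response(fs)
  len <- length(h_true$h)
  n_rec <- length(trial$z$values)
  m <- 50
  starts <- as.integer(seq(500, by = 2 * len, length.out = m))
  sched1 <- contact_schedule_for_test(starts[1], fs, n = n_rec)
  schedm <- contact_schedule_for_test(starts, fs, n = n_rec)
  zm <- compose_sensory(trial$r, render_exafferent(schedm, h_true, n_rec))

  # exact prediction: windows are non-overlapping, so subtraction recovers
  # the response exactly, from one window or averaged over many
  expect_equal(infer_contact_response(zm, trial$r, sched1, len)$h,
               h_true$h, tolerance = 1e-12)
  expect_equal(infer_contact_response(zm, trial$r, schedm, len)$h,
               h_true$h, tolerance = 1e-12)

  # averaging over many contacts suppresses prediction noise ~ 1/sqrt(m)
  noise <- whisk_ts(trial$r$values +
                      withr::with_seed(21, rnorm(n_rec, sd = 0.5)),
                    fs)
  err1 <- sqrt(mean((infer_contact_response(zm, noise, sched1, len)$h -
                       h_true$h)^2))
  errm <- sqrt(mean((infer_contact_response(zm, noise, schedm, len)$h -
                       h_true$h)^2))
  expect_lt(errm, err1 / 4)      # expect roughly sqrt(50) ~ 7x reduction
  expect_gt(errm, err1 / 15)
  expect_error(infer_contact_response(zm, noise,
                                      contact_schedule_for_test(integer(0),
                                                                fs),
                                      len),
               "no contacts")
})
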