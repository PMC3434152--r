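# Shared fixtures, built in code at test time.

test_plant <- function(fs = 200) default_plant(sample_rate_hz = fs)

# Short ringing transient used where the amplitude-calibrated default
# response is unnecessary.
test_response <- function(fs = 200, amp = 3) {
  t <- (0:(round(0.2 * fs) - 1)) / fs
  contact_response(amp * exp(-t / 0.05) * cos(2 * pi * 15 * t), fs)
}

# Build a contact schedule from explicit sample indices.
contact_schedule_for_test <- function(times, fs, n = max(times, 1L) + 200L) {
  whisknovelty:::contact_schedule(as.integer(times), threshold = 0.999,
                                  duration_s = n / fs, sample_rate_hz = fs)
}

# Simulate one contact-laden scenario trial; returns u, r, x, z, schedule.
test_trial <- function(k = 0, duration_s = 60, seed = 1, fs = 200,
                       drive = c("periodic", "stochastic"),
                       contact_threshold = 0.999) {
  drive <- match.arg(drive)
  plant <- test_plant(fs)
  u <- if (drive == "periodic") {
    make_sine(3, sqrt(2), duration_s, fs)
  } else {
    make_bandpass_noise(2, 4, duration_s, fs, seed = seed)
  }
  schedule <- generate_contact_schedule(duration_s, fs, contact_threshold,
                                        seed = seed + 1)
  r <- simulate_reafferent(bilinear_plant(plant, k), u)
  x <- render_exafferent(schedule, test_response(fs), length(r$values))
  list(u = u, r = r, x = x, z = compose_sensory(r, x), schedule = schedule,
       plant = plant)
}
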