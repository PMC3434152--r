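#' Bernoulli contact schedule
#'
#' Draws one uniform sample per time step and schedules a contact wherever
#' the draw exceeds `threshold` (default 0.999, i.e. on average one contact
#' per 5 s at 200 Hz), so contact times are independent and memoryless.
#' Contacts may fall arbitrarily close together; no refractory constraint
#' is imposed at generation.
#'
#' @param duration_s,sample_rate_hz Record duration and sample rate.
#' @param threshold Uniform-draw threshold in `(0, 1]`; `1` gives an empty
#'   schedule.
#' @param seed Integer seed; the schedule is reproducible per seed.
#'
#' @return An object of class `contact_schedule` with 1-based sample
#'   indices in `$times` (use [contact_times()] for seconds).
#' @export
generate_contact_schedule <- function(duration_s, sample_rate_hz,
                                      threshold = 0.999, seed) {
  check_rate_duration(sample_rate_hz, duration_s)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold) || threshold <= 0 || threshold > 1) {
    stop_invalid("`threshold` must lie in (0, 1]")
  }
  n <- round(duration_s * sample_rate_hz)
  draws <- with_seed(seed, runif(n))
  contact_schedule(which(draws > threshold), threshold, duration_s,
                   sample_rate_hz, seed)
}

contact_schedule <- function(times, threshold, duration_s, sample_rate_hz,
                             seed = NA) {
  times <- as.integer(times)
  n <- round(duration_s * sample_rate_hz)
  if (any(diff(times) <= 0)) stop_invalid("contact indices must be increasing")
  if (length(times) && (times[1] < 1L || times[length(times)] > n)) {
    stop_invalid("contact indices must lie within the record")
  }
  structure(list(times = times, threshold = threshold,
                 duration_s = duration_s, sample_rate_hz = sample_rate_hz,
                 seed = seed),
            class = "contact_schedule")
}

#' @export
print.contact_schedule <- function(x, ...) {
  cat(sprintf("<contact_schedule> %d contacts over %g s @ %g Hz (threshold %g)\n",
              length(x$times), x$duration_s, x$sample_rate_hz, x$threshold))
  invisible(x)
}

#' Contact times in seconds
#'
#' @param schedule A `contact_schedule`.
#' @return Numeric vector of contact onset times in seconds.
#' @export
contact_times <- function(schedule) {
  (schedule$times - 1) / schedule$sample_rate_hz
}

#' Contact impulse response
#'
#' The finite impulse response rendering one whisker-object contact into an
#' exafferent transient.
#'
#' @param h Numeric impulse-response sequence (finite values, length >= 1).
#' @param sample_rate_hz Sample rate the response is valid at.
#'
#' @return An object of class `contact_response`.
#' @export
contact_response <- function(h, sample_rate_hz) {
  h <- as.numeric(h)
  if (length(h) < 1L || !all(is.finite(h))) {
    stop_invalid("`h` must be a non-empty finite sequence")
  }
  check_rate_duration(sample_rate_hz, 1)
  structure(list(h = h, sample_rate_hz = as.numeric(sample_rate_hz)),
            class = "contact_response")
}

#' @export
print.contact_response <- function(x, ...) {
  cat(sprintf("<contact_response> %d samples (%.0f ms) @ %g Hz, peak |h| = %.4g\n",
              length(x$h), 1000 * length(x$h) / x$sample_rate_hz,
              x$sample_rate_hz, max(abs(x$h))))
  invisible(x)
}

#' Default contact transient
#'
#' A synthetic stand-in for a measured whisker contact: an exponentially
#' decaying cosine (default 15 Hz, 200 ms long, 50 ms decay constant), the
#' brief ringing of a struck cantilever. Its peak amplitude is scaled to
#' `amplitude_ratio` times the RMS of the plant's reafferent response to
#' the rat-like sawtooth whisking drive, so contacts are prominent but do
#' not dwarf the self-generated background.
#'
#' @param plant A `linear_plant` or `bilinear_plant` used for amplitude
#'   calibration.
#' @param freq_hz Ringing frequency in Hz.
#' @param duration_s Response length in seconds.
#' @param decay_s Exponential decay time constant in seconds.
#' @param amplitude_ratio Peak amplitude over reafferent RMS.
#'
#' @return A [contact_response()].
#' @export
default_contact_response <- function(plant, freq_hz = 15, duration_s = 0.2,
                                     decay_s = 0.05, amplitude_ratio = 3) {
  plant <- as_bilinear(plant)
  fs <- plant$linear$sample_rate_hz
  drive <- make_whisk_sawtooth(duration_s = 30, sample_rate_hz = fs)
  r <- simulate_reafferent(plant, drive)
  # drop the filter/plant settling transient before measuring RMS
  tail_vals <- r$values[-seq_len(round(5 * fs))]
  rms <- sqrt(mean(tail_vals^2))
  t <- (0:(round(duration_s * fs) - 1)) / fs
  shape <- exp(-t / decay_s) * cos(2 * pi * freq_hz * t)
  contact_response(amplitude_ratio * rms * shape / max(abs(shape)), fs)
}

#' Render the exafferent signal from a contact schedule
#'
#' Superposes one copy of the contact impulse response at each scheduled
#' contact index; copies from nearby contacts sum sample-wise and the last
#' copies are truncated at the record end. Linear in the schedule.
#'
#' @param schedule A `contact_schedule`.
#' @param response A [contact_response()] at the same rate.
#' @param n_samples Output length in samples.
#'
#' @return The exafferent signal as a [whisk_ts()].
#' @export
render_exafferent <- function(schedule, response, n_samples) {
  if (!inherits(schedule, "contact_schedule")) {
    stop_invalid("`schedule` must be a contact_schedule")
  }
  if (!inherits(response, "contact_response")) {
    stop_invalid("`response` must be a contact_response")
  }
  if (schedule$sample_rate_hz != response$sample_rate_hz) {
    stop_invalid("schedule and response sample rates differ")
  }
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 1L) {
    stop_invalid("`n_samples` must be a positive integer")
  }
  x <- numeric(n_samples)
  h <- response$h
  for (j in schedule$times) {
    if (j > n_samples) next
    span <- j:min(n_samples, j + length(h) - 1L)
    x[span] <- x[span] + h[seq_along(span)]
  }
  whisk_ts(x, schedule$sample_rate_hz)
}

#' Compose the observed sensory signal
#'
#' The additive signal model: the sensor observes the sum of the reafferent
#' (self-generated) and exafferent (contact) components, `z = r + x`.
#'
#' @param r,x Reafferent and exafferent [whisk_ts()] of equal length and
#'   rate.
#'
#' @return The observed sensory signal as a [whisk_ts()].
#' @export
compose_sensory <- function(r, x) {
  assert_ts(r); assert_ts(x)
  assert_same_grid(r, x)
  whisk_ts(r$values + x$values, r$sample_rate_hz, r$t0_s)
}

#' Infer the contact response from prediction residuals
#'
#' Contact transients are not observed directly; they are estimated as the
#' average, over contacts, of the difference between the observed sensory
#' signal and the reafferent-model prediction on a fixed window starting at
#' each contact. Windows that would run past the record end are dropped.
#'
#' @param z Observed sensory signal ([whisk_ts()]).
#' @param r_pred Reafferent-model prediction, same length and rate.
#' @param schedule A `contact_schedule` aligned with `z`.
#' @param length_samples Window length in samples.
#'
#' @return A [contact_response()] holding the averaged residual window.
#' @export
infer_contact_response <- function(z, r_pred, schedule, length_samples) {
  assert_ts(z); assert_ts(r_pred)
  assert_same_grid(z, r_pred)
  length_samples <- as.integer(length_samples)
  if (is.na(length_samples) || length_samples < 1L) {
    stop_invalid("`length_samples` must be a positive integer")
  }
  diff_sig <- z$values - r_pred$values
  starts <- schedule$times[schedule$times + length_samples - 1L <=
                             length(diff_sig)]
  if (length(starts) == 0L) {
    stop_invalid("no contacts with a complete window available")
  }
  acc <- numeric(length_samples)
  for (j in starts) acc <- acc + diff_sig[j:(j + length_samples - 1L)]
  contact_response(acc / length(starts), z$sample_rate_hz)
}
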