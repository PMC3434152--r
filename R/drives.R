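#' Sinusoidal whisking drive
#'
#' Generates the periodic whisking motor command: a pure sine wave. The
#' periodic drive used in the simulated experiments is a 3 Hz sine; its
#' default amplitude of `sqrt(2)` gives the drive unit RMS so that periodic
#' and stochastic whisking inject equal power into the plant.
#'
#' @param freq_hz Sine frequency in Hz; must be below Nyquist.
#' @param amplitude Peak amplitude (default `sqrt(2)`, i.e. unit RMS).
#' @param duration_s Record duration in seconds.
#' @param sample_rate_hz Sample rate in Hz (working rate 200 Hz).
#' @param phase_rad Initial phase in radians.
#'
#' @return A [whisk_ts()].
#' @examples
#' u <- make_sine(3, 1, 1, 200)
#' u$values[1] # 0 at phase 0
#' @export
make_sine <- function(freq_hz, amplitude = sqrt(2), duration_s,
                      sample_rate_hz, phase_rad = 0) {
  check_rate_duration(sample_rate_hz, duration_s)
  if (!is.finite(freq_hz) || freq_hz <= 0) {
    stop_invalid("`freq_hz` must be positive")
  }
  if (freq_hz >= sample_rate_hz / 2) {
    stop_invalid("`freq_hz` (%g Hz) must be below Nyquist (%g Hz)",
                 freq_hz, sample_rate_hz / 2)
  }
  n <- round(duration_s * sample_rate_hz)
  i <- 0:(n - 1)
  whisk_ts(amplitude * sin(2 * pi * freq_hz * i / sample_rate_hz + phase_rad),
           sample_rate_hz)
}

#' Sawtooth-like whisking drive
#'
#' A rat-like protraction/retraction pattern: a unit square wave (levels
#' +1/-1, high for `duty_fraction` of each cycle) passed through a causal
#' first-order low-pass filter. The filter is the exact zero-order-hold
#' discretization of `dy/dt = (u - y) / tau`, so the stated continuous time
#' constant holds at any sample rate. With the defaults (3 Hz, 40% duty,
#' 60 ms time constant) the output shows the fast/slow asymmetry of rodent
#' whisking.
#'
#' @param freq_hz Whisk cycle frequency in Hz.
#' @param duty_fraction Fraction of each cycle spent at the high level,
#'   strictly between 0 and 1.
#' @param tau_s First-order filter time constant in seconds.
#' @param duration_s,sample_rate_hz Record duration and sample rate.
#' @param amplitude Output scale factor applied after filtering.
#'
#' @return A [whisk_ts()].
#' @export
make_whisk_sawtooth <- function(freq_hz = 3, duty_fraction = 0.4,
                                tau_s = 0.06, duration_s, sample_rate_hz,
                                amplitude = 1) {
  check_rate_duration(sample_rate_hz, duration_s)
  if (!is.finite(freq_hz) || freq_hz <= 0 || freq_hz >= sample_rate_hz / 2) {
    stop_invalid("`freq_hz` must be positive and below Nyquist")
  }
  if (!is.finite(duty_fraction) || duty_fraction <= 0 || duty_fraction >= 1) {
    stop_invalid("`duty_fraction` must lie strictly between 0 and 1")
  }
  if (!is.finite(tau_s) || tau_s <= 0) stop_invalid("`tau_s` must be positive")
  n <- round(duration_s * sample_rate_hz)
  phase <- (0:(n - 1)) * freq_hz / sample_rate_hz
  square <- ifelse(phase - floor(phase) < duty_fraction, 1, -1)
  # exact ZOH of dy/dt = (u - y)/tau: y[i] = a*y[i-1] + (1-a)*u[i],
  # with u held over the interval ending at sample i
  a <- exp(-1 / (tau_s * sample_rate_hz))
  y <- as.numeric(signal::filter(c(1 - a), c(1, -a), square))
  whisk_ts(amplitude * y, sample_rate_hz)
}

#' Band-pass filtered Gaussian noise drive
#'
#' The stochastic whisking motor command: Gaussian white noise passed once
#' through a causal 8th-order Butterworth band-pass filter (default pass
#' band 2-4 Hz; the steep skirts keep over 90% of the output power inside
#' the band), then rescaled to unit sample variance. Deterministic for a
#' given seed; the caller's RNG state is left untouched.
#'
#' @param low_hz,high_hz Pass-band edges in Hz, `0 < low_hz < high_hz <`
#'   Nyquist.
#' @param duration_s,sample_rate_hz Record duration and sample rate.
#' @param seed Integer seed for the noise generator.
#'
#' @return A [whisk_ts()] with unit sample variance.
#' @export
make_bandpass_noise <- function(low_hz = 2, high_hz = 4, duration_s,
                                sample_rate_hz, seed) {
  check_rate_duration(sample_rate_hz, duration_s)
  if (!is.finite(low_hz) || !is.finite(high_hz) || low_hz <= 0 ||
      low_hz >= high_hz || high_hz >= sample_rate_hz / 2) {
    stop_invalid("band edges must satisfy 0 < low_hz < high_hz < Nyquist")
  }
  n <- round(duration_s * sample_rate_hz)
  w <- with_seed(seed, rnorm(n))
  bf <- signal::butter(4, c(low_hz, high_hz) / (sample_rate_hz / 2),
                       type = "pass")
  x <- as.numeric(signal::filter(bf, w))
  whisk_ts(x / sd(x), sample_rate_hz)
}

#' Low-pass filter and decimate a time series
#'
#' Pre-processing applied to high-rate recordings before analysis: a causal
#' 4th-order Butterworth low-pass at `cutoff_hz` followed by integer
#' decimation to `target_rate_hz` (e.g. 2 kHz recordings low-passed at
#' 10 Hz and brought down to the 200 Hz working rate).
#'
#' @param ts A [whisk_ts()].
#' @param cutoff_hz Low-pass cutoff in Hz; must be below the target Nyquist.
#' @param target_rate_hz Output sample rate; must divide `ts$sample_rate_hz`
#'   exactly.
#'
#' @return A [whisk_ts()] at `target_rate_hz`.
#' @export
lowpass_downsample <- function(ts, cutoff_hz, target_rate_hz) {
  assert_ts(ts)
  if (!is.finite(cutoff_hz) || cutoff_hz <= 0) {
    stop_invalid("`cutoff_hz` must be positive")
  }
  factor <- ts$sample_rate_hz / target_rate_hz
  if (!is.finite(factor) || factor < 1 ||
      abs(factor - round(factor)) > 1e-9) {
    stop_invalid("`target_rate_hz` (%g) must divide the input rate (%g) exactly",
                 target_rate_hz, ts$sample_rate_hz)
  }
  if (cutoff_hz >= target_rate_hz / 2) {
    stop_invalid("`cutoff_hz` must be below the target Nyquist (%g Hz)",
                 target_rate_hz / 2)
  }
  bf <- signal::butter(4, cutoff_hz / (ts$sample_rate_hz / 2), type = "low")
  y <- as.numeric(signal::filter(bf, ts$values))
  keep <- seq(1, length(y), by = round(factor))
  whisk_ts(y[keep], target_rate_hz, t0_s = ts$t0_s)
}

#' One-sided periodogram
#'
#' Plain periodogram `|FFT|^2 / n` of a time series, reported on the
#' one-sided frequency grid in Hz. No tapering, padding or detrending is
#' applied, so a sinusoid spanning an integer number of periods falls on a
#' single bin.
#'
#' @param ts A [whisk_ts()].
#' @param discard_s Initial transient to drop before the transform, in
#'   seconds (default 0).
#'
#' @return A data frame with columns `freq_hz` and `power`.
#' @export
periodogram <- function(ts, discard_s = 0) {
  assert_ts(ts)
  x <- ts$values
  drop <- round(discard_s * ts$sample_rate_hz)
  if (drop >= length(x)) stop_invalid("`discard_s` leaves no samples")
  if (drop > 0) x <- x[-seq_len(drop)]
  n <- length(x)
  p <- Mod(fft(x))^2 / n
  half <- seq_len(floor(n / 2) + 1L)
  data.frame(freq_hz = (half - 1) * ts$sample_rate_hz / n,
             power = p[half])
}

#' Spectral peaks of a periodogram
#'
#' Local maxima of a periodogram whose power exceeds a fraction of the
#' strongest peak. Used to compare harmonic content between linear and
#' bilinear plant output.
#'
#' @param pg A data frame as returned by [periodogram()].
#' @param min_rel_power Minimum power relative to the global maximum for a
#'   local maximum to count as a peak.
#'
#' @return A data frame with columns `freq_hz`, `power` and `rel_power`,
#'   ordered by frequency.
#' @export
spectral_peaks <- function(pg, min_rel_power = 0.01) {
  p <- pg$power
  n <- length(p)
  if (n < 3L) stop_invalid("periodogram too short for peak detection")
  left <- c(-Inf, p[-n])
  right <- c(p[-1], -Inf)
  is_peak <- p > left & p >= right & p >= min_rel_power * max(p)
  out <- pg[is_peak, , drop = FALSE]
  out$rel_power <- out$power / max(p)
  rownames(out) <- NULL
  out
}

check_rate_duration <- function(sample_rate_hz, duration_s) {
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      !is.finite(sample_rate_hz) || sample_rate_hz <= 0) {
    stop_invalid("`sample_rate_hz` must be a single positive number")
  }
  if (!is.numeric(duration_s) || length(duration_s) != 1L ||
      !is.finite(duration_s) || duration_s <= 0) {
    stop_invalid("`duration_s` must be a single positive number")
  }
  invisible(TRUE)
}
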