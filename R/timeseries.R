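#' Uniformly sampled time series
#'
#' The single carrier type used throughout the package for motor commands,
#' reafferent and exafferent signals, observed sensory signals, filter
#' predictions and novelty outputs. A `whisk_ts` is a numeric vector of
#' samples together with a fixed sample rate and a start time; sample `i`
#' (1-based) is taken at `t0_s + (i - 1) / sample_rate_hz`.
#'
#' @param values Numeric vector of samples; all values must be finite.
#' @param sample_rate_hz Positive sample rate in Hz.
#' @param t0_s Start time of the first sample, in seconds.
#'
#' @return An object of class `whisk_ts`.
#' @examples
#' ts <- whisk_ts(sin(2 * pi * 3 * (0:199) / 200), 200)
#' ts_duration(ts)
#' @export
whisk_ts <- function(values, sample_rate_hz, t0_s = 0) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop_invalid("a time series needs at least one sample")
  if (!all(is.finite(values))) stop_invalid("all time-series values must be finite")
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      !is.finite(sample_rate_hz) || sample_rate_hz <= 0) {
    stop_invalid("`sample_rate_hz` must be a single positive number")
  }
  if (!is.numeric(t0_s) || length(t0_s) != 1L || !is.finite(t0_s)) {
    stop_invalid("`t0_s` must be a single finite number")
  }
  structure(list(values = values,
                 sample_rate_hz = as.numeric(sample_rate_hz),
                 t0_s = as.numeric(t0_s)),
            class = "whisk_ts")
}

is_whisk_ts <- function(x) inherits(x, "whisk_ts")

assert_ts <- function(x, arg = deparse(substitute(x))) {
  if (!is_whisk_ts(x)) stop_invalid("`%s` must be a whisk_ts object", arg)
  invisible(x)
}

#' @export
print.whisk_ts <- function(x, ...) {
  cat(sprintf("<whisk_ts> %d samples @ %g Hz (%.3f s), t0 = %g s\n",
              length(x$values), x$sample_rate_hz,
              length(x$values) / x$sample_rate_hz, x$t0_s))
  cat(sprintf("  range [%.4g, %.4g], rms %.4g\n",
              min(x$values), max(x$values), sqrt(mean(x$values^2))))
  invisible(x)
}

#' @export
length.whisk_ts <- function(x) length(x$values)

#' Time stamps, duration and values of a time series
#'
#' @param ts A [whisk_ts()] object.
#' @return `ts_times` returns the vector of sample times in seconds,
#'   `ts_duration` the record length in seconds, and `ts_values` the bare
#'   numeric sample vector.
#' @export
ts_times <- function(ts) {
  assert_ts(ts)
  ts$t0_s + (seq_along(ts$values) - 1) / ts$sample_rate_hz
}

#' @rdname ts_times
#' @export
ts_duration <- function(ts) {
  assert_ts(ts)
  length(ts$values) / ts$sample_rate_hz
}

#' @rdname ts_times
#' @export
ts_values <- function(ts) {
  assert_ts(ts)
  ts$values
}

# Check two series share a sample rate (and optionally length).
assert_same_grid <- function(a, b, check_length = TRUE) {
  if (a$sample_rate_hz != b$sample_rate_hz) {
    stop_invalid("sample rates differ (%g Hz vs %g Hz)",
                 a$sample_rate_hz, b$sample_rate_hz)
  }
  if (check_length && length(a$values) != length(b$values)) {
    stop_invalid("series lengths differ (%d vs %d)",
                 length(a$values), length(b$values))
  }
  invisible(TRUE)
}
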