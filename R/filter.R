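#' Adaptive filter configuration
#'
#' Settings for the tap-delay LMS filter that predicts the reafferent
#' component of the sensory signal. The filter can be wired from the motor
#' command alone (a forward model), from the sensory signal's own delayed
#' past (a signal model), or from both (sensorimotor). Each enabled input
#' feeds `n_taps_per_input` taps spaced `tap_spacing_s` apart, so the
#' sensorimotor wiring carries twice the taps of the single-input ones.
#' Both input lines are delayed by `processing_delay_s` (default 10 ms,
#' mimicking neural conduction and processing latency); the sensory line
#' gets an additional `sensory_decorrelation_delay_s` (default 100 ms) so
#' its taps cannot simply reproduce an ongoing contact transient and cancel
#' the very events the scheme is meant to expose.
#'
#' @param mode One of `"motor"`, `"sensory"`, `"sensorimotor"`.
#' @param n_taps_per_input Taps per enabled input (default 100).
#' @param tap_spacing_s Spacing between taps in seconds (default 5 ms; one
#'   sample at the 200 Hz working rate).
#' @param learning_rate LMS step size `beta` (default `5e-4`, the slow
#'   rate suited to long simulated records; use about `0.01` for short
#'   recorded snippets).
#' @param processing_delay_s Delay applied to every input line, seconds.
#' @param sensory_decorrelation_delay_s Extra delay on the sensory line,
#'   seconds.
#'
#' @return An object of class `adaptive_filter_config`.
#' @export
adaptive_filter_config <- function(mode = c("motor", "sensory", "sensorimotor"),
                                   n_taps_per_input = 100,
                                   tap_spacing_s = 0.005,
                                   learning_rate = 5e-4,
                                   processing_delay_s = 0.010,
                                   sensory_decorrelation_delay_s = 0.100) {
  mode <- match.arg(mode)
  n_taps_per_input <- as.integer(n_taps_per_input)
  if (is.na(n_taps_per_input) || n_taps_per_input < 1L) {
    stop_invalid("`n_taps_per_input` must be a positive integer")
  }
  if (!is.finite(tap_spacing_s) || tap_spacing_s <= 0) {
    stop_invalid("`tap_spacing_s` must be positive")
  }
  if (!is.finite(learning_rate) || learning_rate < 0) {
    stop_invalid("`learning_rate` must be non-negative")
  }
  if (!is.finite(processing_delay_s) || processing_delay_s < 0 ||
      !is.finite(sensory_decorrelation_delay_s) ||
      sensory_decorrelation_delay_s < 0) {
    stop_invalid("delays must be non-negative")
  }
  structure(list(mode = mode,
                 n_taps_per_input = n_taps_per_input,
                 tap_spacing_s = tap_spacing_s,
                 learning_rate = learning_rate,
                 processing_delay_s = processing_delay_s,
                 sensory_decorrelation_delay_s = sensory_decorrelation_delay_s),
            class = "adaptive_filter_config")
}

n_total_taps <- function(config) {
  config$n_taps_per_input * if (config$mode == "sensorimotor") 2L else 1L
}

# Convert the config's continuous-time settings to sample counts, erroring
# if they do not land on the sample grid.
config_samples <- function(config, sample_rate_hz) {
  as_samples <- function(x, what) {
    s <- x * sample_rate_hz
    if (abs(s - round(s)) > 1e-9) {
      stop_invalid("%s (%g s) is not a whole number of samples at %g Hz",
                   what, x, sample_rate_hz)
    }
    as.integer(round(s))
  }
  stride <- as_samples(config$tap_spacing_s, "`tap_spacing_s`")
  if (stride < 1L) stop_invalid("`tap_spacing_s` is below one sample")
  delay_m <- as_samples(config$processing_delay_s, "`processing_delay_s`")
  delay_s <- delay_m + as_samples(config$sensory_decorrelation_delay_s,
                                  "`sensory_decorrelation_delay_s`")
  list(stride = stride, delay_m = delay_m, delay_s = delay_s)
}

#' Step-wise adaptive filter state
#'
#' Explicit single-sample interface to the adaptive filter, exposing the
#' analysis (tap-delay), synthesis (weighted sum) and adaptation (LMS)
#' stages separately. [run_novelty_scheme()] is the fast whole-record
#' equivalent; this interface exists for inspection and for driving the
#' filter inside custom loops. Weights start at zero and tap buffers start
#' empty (zero-padded).
#'
#' @param config An [adaptive_filter_config()].
#' @param sample_rate_hz Working sample rate in Hz.
#'
#' @return An object of class `adaptive_filter_state` with fields
#'   `weights`, `config`, and internal input-history buffers.
#' @export
adaptive_filter_state <- function(config, sample_rate_hz = 200) {
  if (!inherits(config, "adaptive_filter_config")) {
    stop_invalid("`config` must be an adaptive_filter_config")
  }
  geom <- config_samples(config, sample_rate_hz)
  hist_len <- max(geom$delay_m, geom$delay_s) +
    (config$n_taps_per_input - 1L) * geom$stride + 1L
  structure(list(config = config,
                 sample_rate_hz = sample_rate_hz,
                 geom = geom,
                 weights = numeric(n_total_taps(config)),
                 buf_u = numeric(hist_len),
                 buf_z = numeric(hist_len)),
            class = "adaptive_filter_state")
}

#' Advance the tap buffers and assemble the component vector
#'
#' Pushes one new motor and sensory sample into the filter's history
#' buffers and returns the component (tap) vector `p` seen by the weights
#' at this time step: per enabled input, `n_taps_per_input` delayed samples
#' at the configured spacing, the motor line delayed by the processing
#' delay and the sensory line by the processing plus decorrelation delay.
#'
#' @param state An [adaptive_filter_state()].
#' @param u_t Current motor-command sample (ignored in sensory mode).
#' @param z_t Current sensory sample (ignored in motor mode).
#'
#' @return A list with the updated `state` and the component vector `p`.
#' @export
assemble_components <- function(state, u_t, z_t) {
  if (!inherits(state, "adaptive_filter_state")) {
    stop_invalid("`state` must be an adaptive_filter_state")
  }
  # buffers store newest sample first
  state$buf_u <- c(u_t, state$buf_u[-length(state$buf_u)])
  state$buf_z <- c(z_t, state$buf_z[-length(state$buf_z)])
  cfg <- state$config
  geom <- state$geom
  tap_at <- function(buf, delay) {
    idx <- 1L + delay + (seq_len(cfg$n_taps_per_input) - 1L) * geom$stride
    buf[idx]
  }
  p <- switch(cfg$mode,
    motor = tap_at(state$buf_u, geom$delay_m),
    sensory = tap_at(state$buf_z, geom$delay_s),
    sensorimotor = c(tap_at(state$buf_u, geom$delay_m),
                     tap_at(state$buf_z, geom$delay_s)))
  list(state = state, p = p)
}

#' Filter prediction from a component vector
#'
#' The synthesis stage: the predicted reafference is the inner product of
#' the weight vector with the component vector, `yhat = sum(w * p)`. Has no
#' side effects on the state.
#'
#' @param state An [adaptive_filter_state()].
#' @param p Component vector from [assemble_components()].
#'
#' @return The scalar prediction.
#' @export
filter_predict <- function(state, p) {
  if (length(p) != length(state$weights)) {
    stop_invalid("component vector length (%d) does not match weights (%d)",
                 length(p), length(state$weights))
  }
  sum(state$weights * p)
}

#' LMS weight update
#'
#' The adaptation stage: `w <- w + beta * p * e`, correlating each
#' component with the novelty (error) signal `e = z - yhat`. This is the
#' standard least-mean-squares rule; in the cerebellar reading the teaching
#' signal is the negated novelty output and positive correlation depresses
#' the synaptic weight, which yields the identical net weight change.
#'
#' @param state An [adaptive_filter_state()].
#' @param p Component vector used for the prediction at this step.
#' @param e_t Scalar novelty/error sample; must be finite.
#'
#' @return The updated state.
#' @export
lms_update <- function(state, p, e_t) {
  if (!is.finite(e_t)) {
    stop_invalid("weight update diverged: non-finite error signal")
  }
  if (length(p) != length(state$weights)) {
    stop_invalid("component vector length (%d) does not match weights (%d)",
                 length(p), length(state$weights))
  }
  state$weights <- state$weights + state$config$learning_rate * p * e_t
  state
}

#' Run the novelty-detection scheme over a record
#'
#' Per sample: assemble the component vector, predict the reafference,
#' emit the novelty signal `e[t] = z[t] - yhat[t]`, and apply the LMS
#' update. The loop runs in compiled code; output is deterministic given
#' the inputs. Weight snapshots are retained every `snapshot_every_s`
#' seconds for diagnostics.
#'
#' @param u Motor command [whisk_ts()] (may be `NULL` in sensory mode).
#' @param z Observed sensory signal [whisk_ts()].
#' @param config An [adaptive_filter_config()].
#' @param init_weights Optional initial weight vector (default all zero).
#' @param snapshot_every_s Snapshot period in seconds; `0` disables.
#'
#' @return A list of class `novelty_run` with elements `e` and `yhat`
#'   ([whisk_ts()]), the final `weights`, a `snapshots` matrix (one row per
#'   snapshot), `snapshot_times_s`, and the `config`.
#' @export
run_novelty_scheme <- function(u, z, config, init_weights = NULL,
                               snapshot_every_s = 10) {
  if (!inherits(config, "adaptive_filter_config")) {
    stop_invalid("`config` must be an adaptive_filter_config")
  }
  assert_ts(z)
  if (anyNA(z$values)) stop_invalid("NaN/NA in sensory input")
  if (config$mode == "sensory") {
    if (is.null(u)) u <- whisk_ts(numeric(length(z$values)), z$sample_rate_hz)
  }
  assert_ts(u)
  if (anyNA(u$values)) stop_invalid("NaN/NA in motor input")
  assert_same_grid(u, z)
  geom <- config_samples(config, z$sample_rate_hz)
  n_total <- n_total_taps(config)
  if (is.null(init_weights)) init_weights <- numeric(n_total)
  if (length(init_weights) != n_total) {
    stop_invalid("`init_weights` must have length %d", n_total)
  }
  mode_code <- match(config$mode, c("motor", "sensory", "sensorimotor")) - 1L
  snap_n <- if (snapshot_every_s > 0) {
    as.integer(round(snapshot_every_s * z$sample_rate_hz))
  } else 0L
  res <- lms_novelty_cpp(u$values, z$values, config$n_taps_per_input,
                         geom$stride, geom$delay_m, geom$delay_s, mode_code,
                         config$learning_rate, init_weights, snap_n)
  structure(list(e = whisk_ts(res$e, z$sample_rate_hz, z$t0_s),
                 yhat = whisk_ts(res$yhat, z$sample_rate_hz, z$t0_s),
                 weights = res$weights,
                 snapshots = res$snapshots,
                 snapshot_times_s = res$snapshot_sample / z$sample_rate_hz,
                 config = config),
            class = "novelty_run")
}

#' @export
print.novelty_run <- function(x, ...) {
  cat(sprintf("<novelty_run> mode '%s', %d taps, beta = %g\n",
              x$config$mode, length(x$weights), x$config$learning_rate))
  cat(sprintf("  %d samples @ %g Hz; final-window e RMS %.4g\n",
              length(x$e$values), x$e$sample_rate_hz,
              sqrt(mean(tail(x$e$values, length(x$e$values) %/% 5)^2))))
  invisible(x)
}

#' @importFrom utils tail
NULL
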