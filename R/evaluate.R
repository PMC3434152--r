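#' Signal-to-noise ratio around contact events
#'
#' Scores how well a signal exposes contacts: the "signal" is the variance
#' of samples falling in the union of post-contact windows (default 200 ms
#' from each contact onset), the "noise" is the variance of all remaining
#' samples, and the SNR is their ratio in decibels. Only samples from
#' `eval_start_s` onward are scored, so early weight adaptation does not
#' distort the result; the default evaluation window is the final fifth of
#' the record (the final 200 s of a 1000 s run). Windows overlapping the
#' record end are truncated; overlapping windows count each sample once.
#'
#' @param sig The scored [whisk_ts()] (a novelty output or the raw signal).
#' @param schedule The `contact_schedule` the record was generated with.
#' @param post_window_s Post-contact window length in seconds.
#' @param eval_start_s Start of the evaluation window in seconds; `NULL`
#'   means 80% of the record duration.
#'
#' @return An object of class `snr_result` with fields `signal_variance`,
#'   `noise_variance`, `snr_db`, `eval_start_s`, `post_window_s`.
#' @export
compute_snr <- function(sig, schedule, post_window_s = 0.2,
                        eval_start_s = NULL) {
  assert_ts(sig)
  if (!inherits(schedule, "contact_schedule")) {
    stop_invalid("`schedule` must be a contact_schedule")
  }
  if (sig$sample_rate_hz != schedule$sample_rate_hz) {
    stop_invalid("signal and schedule sample rates differ")
  }
  n <- length(sig$values)
  if (is.null(eval_start_s)) eval_start_s <- 0.8 * n / sig$sample_rate_hz
  start_idx <- round(eval_start_s * sig$sample_rate_hz) + 1L
  if (start_idx < 1L || start_idx >= n) {
    stop_invalid("`eval_start_s` must fall inside the record")
  }
  win <- as.integer(round(post_window_s * sig$sample_rate_hz))
  if (win < 1L) stop_invalid("`post_window_s` is below one sample")
  in_signal <- logical(n)
  for (j in schedule$times) {
    in_signal[j:min(n, j + win - 1L)] <- TRUE
  }
  scored <- start_idx:n
  sig_idx <- scored[in_signal[scored]]
  noise_idx <- scored[!in_signal[scored]]
  if (length(sig_idx) < 2L) {
    stop_invalid("no post-contact samples in the evaluation window")
  }
  if (length(noise_idx) < 2L) {
    stop_invalid("no noise-region samples in the evaluation window")
  }
  sv <- var(sig$values[sig_idx])
  nv <- var(sig$values[noise_idx])
  structure(list(signal_variance = sv, noise_variance = nv,
                 snr_db = 10 * log10(sv / nv),
                 eval_start_s = eval_start_s, post_window_s = post_window_s),
            class = "snr_result")
}

#' @export
print.snr_result <- function(x, ...) {
  cat(sprintf("<snr_result> %.2f dB (signal var %.4g, noise var %.4g; eval from %g s)\n",
              x$snr_db, x$signal_variance, x$noise_variance, x$eval_start_s))
  invisible(x)
}

#' SNR improvement of a novelty scheme over the raw signal
#'
#' The headline performance metric: the contact SNR of the scheme output
#' minus the contact SNR of the raw sensory signal, in decibels, both
#' computed with [compute_snr()] against the same contact schedule and
#' evaluation window.
#'
#' @param scheme_output Novelty signal [whisk_ts()].
#' @param raw Raw sensory signal [whisk_ts()], aligned with
#'   `scheme_output`.
#' @inheritParams compute_snr
#'
#' @return Improvement in dB (a bare number).
#' @export
snr_improvement <- function(scheme_output, raw, schedule, post_window_s = 0.2,
                            eval_start_s = NULL) {
  out <- compute_snr(scheme_output, schedule, post_window_s, eval_start_s)
  base <- compute_snr(raw, schedule, post_window_s, eval_start_s)
  out$snr_db - base$snr_db
}

#' Threshold-crossing contact detector
#'
#' Signals a contact wherever the rectified novelty signal `|e|` crosses a
#' threshold from below, then holds off further events for a refractory
#' period. When a reference schedule is supplied, each event falling within
#' the post-contact window of a true contact is counted as a hit and every
#' other event as a false alarm.
#'
#' @param e Novelty signal [whisk_ts()].
#' @param threshold Positive detection threshold applied to `|e|`.
#' @param refractory_s Minimum separation between events, seconds.
#' @param reference Optional `contact_schedule` of true contacts.
#' @param post_window_s Window after each true contact within which an
#'   event counts as a hit.
#'
#' @return An object of class `detection_result`: `times_s` of detected
#'   events, the threshold and refractory period used, and (given a
#'   reference) `n_hits`, `hit_rate`, `n_false_alarms`,
#'   `false_alarm_rate_hz`.
#' @export
detect_contacts <- function(e, threshold, refractory_s = 0.1,
                            reference = NULL, post_window_s = 0.2) {
  assert_ts(e)
  if (!is.finite(threshold) || threshold <= 0) {
    stop_invalid("`threshold` must be positive")
  }
  if (!is.finite(refractory_s) || refractory_s < 0) {
    stop_invalid("`refractory_s` must be non-negative")
  }
  a <- abs(e$values)
  above <- a >= threshold
  crossing <- which(above & !c(FALSE, above[-length(above)]))
  refr <- round(refractory_s * e$sample_rate_hz)
  events <- integer(0)
  last <- -Inf
  for (i in crossing) {
    if (i - last > refr) {
      events <- c(events, i)
      last <- i
    }
  }
  res <- list(times_s = e$t0_s + (events - 1) / e$sample_rate_hz,
              threshold = threshold, refractory_s = refractory_s)
  if (!is.null(reference)) {
    win <- round(post_window_s * e$sample_rate_hz)
    hit_of <- function(i) any(i >= reference$times & i < reference$times + win)
    is_hit <- vapply(events, hit_of, logical(1))
    contact_hit <- vapply(reference$times, function(j) {
      any(events >= j & events < j + win)
    }, logical(1))
    res$n_hits <- sum(is_hit)
    res$hit_rate <- if (length(reference$times)) {
      mean(contact_hit)
    } else NA_real_
    res$n_false_alarms <- sum(!is_hit)
    res$false_alarm_rate_hz <-
      sum(!is_hit) / (length(e$values) / e$sample_rate_hz)
  }
  structure(res, class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result> %d events (threshold %g, refractory %g s)\n",
              length(x$times_s), x$threshold, x$refractory_s))
  if (!is.null(x$hit_rate)) {
    cat(sprintf("  hit rate %.3f, false alarms %.3f /s\n",
                x$hit_rate, x$false_alarm_rate_hz))
  }
  invisible(x)
}

#' Default detection threshold from the noise region
#'
#' A robust threshold for [detect_contacts()]: a multiple (default 4) of
#' the scaled median absolute deviation of the novelty signal over the
#' samples outside all post-contact windows in the evaluation region.
#'
#' @param e Novelty signal [whisk_ts()].
#' @param schedule True `contact_schedule`.
#' @param mult Threshold multiplier.
#' @inheritParams compute_snr
#'
#' @return A positive threshold.
#' @export
detection_threshold <- function(e, schedule, mult = 4, post_window_s = 0.2,
                                eval_start_s = NULL) {
  assert_ts(e)
  n <- length(e$values)
  if (is.null(eval_start_s)) eval_start_s <- 0.8 * n / e$sample_rate_hz
  start_idx <- round(eval_start_s * e$sample_rate_hz) + 1L
  win <- round(post_window_s * e$sample_rate_hz)
  in_signal <- logical(n)
  for (j in schedule$times) in_signal[j:min(n, j + win - 1L)] <- TRUE
  noise <- e$values[start_idx:n][!in_signal[start_idx:n]]
  mult * mad(noise)
}
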