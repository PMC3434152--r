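#' Run the whisking scenario grid
#'
#' The package's main experiment: for each combination of whisking mode
#' (stochastic band-pass noise or periodic 3 Hz sine, both unit RMS) and
#' bilinear coefficient `k`, repeated trials simulate the plant with
#' Bernoulli contacts and score each novelty scheme's SNR improvement over
#' the raw sensory signal. Trials draw fresh contact (and, for stochastic
#' whisking, drive) seeds derived deterministically from `base_seed`, so a
#' grid is exactly reproducible. A trial whose simulation or adaptation
#' diverges is recorded with `NA` improvement and a warning; the grid
#' errors if more than 10% of trials fail.
#'
#' @param plant A `linear_plant`; the grid supplies each `k` itself.
#' @param whisking Character subset of `c("stochastic", "periodic")`.
#' @param k Numeric vector of bilinear coefficients (default `c(0, 0.05)`).
#' @param schemes Character subset of
#'   `c("sensory", "motor", "sensorimotor")`.
#' @param duration_s Trial length in seconds (default 1000).
#' @param n_trials Trials per grid cell (default 20).
#' @param base_seed Integer master seed.
#' @param contact_threshold Bernoulli threshold for contact generation.
#' @param response A [contact_response()]; `NULL` builds
#'   [default_contact_response()] from the linear plant once, so the same
#'   transient is used in every cell.
#' @param filter_config An [adaptive_filter_config()] used as template;
#'   its `mode` is overridden per scheme.
#' @param eval_start_s Evaluation window start; `NULL` means 80% of
#'   `duration_s`.
#' @param drive_freq_hz Periodic drive frequency in Hz.
#' @param drive_band_hz Stochastic drive pass band, Hz.
#'
#' @return A data frame of class `scenario_grid` with one row per
#'   (whisking, k, scheme, trial): columns `whisking`, `k`, `scheme`,
#'   `trial`, `snr_db`, `improvement_db`, `n_contacts`, `seed`. Rows with
#'   `scheme == "raw"` carry the baseline SNR (improvement 0).
#' @seealso [aggregate_scenarios()] for mean +/- sd summaries.
#' @export
run_scenario_grid <- function(plant = default_plant(),
                              whisking = c("stochastic", "periodic"),
                              k = c(0, 0.05),
                              schemes = c("sensory", "motor", "sensorimotor"),
                              duration_s = 1000, n_trials = 20, base_seed = 1,
                              contact_threshold = 0.999, response = NULL,
                              filter_config = adaptive_filter_config(),
                              eval_start_s = NULL,
                              drive_freq_hz = 3, drive_band_hz = c(2, 4)) {
  if (!inherits(plant, "linear_plant")) {
    stop_invalid("`plant` must be a linear_plant (k is supplied by the grid)")
  }
  whisking <- match.arg(whisking, several.ok = TRUE)
  schemes <- match.arg(schemes, several.ok = TRUE)
  fs <- plant$sample_rate_hz
  if (is.null(response)) response <- default_contact_response(plant)
  if (is.null(eval_start_s)) eval_start_s <- 0.8 * duration_s

  rows <- list()
  n_failed <- 0L
  n_cells <- 0L
  for (wmode in whisking) for (kk in sort(k)) {
    bp <- bilinear_plant(plant, kk)
    for (trial in seq_len(n_trials)) {
      n_cells <- n_cells + 1L
      seed <- trial_seed(base_seed, match(wmode, c("stochastic", "periodic")),
                         which(sort(k) == kk)[1], trial)
      out <- tryCatch(
        run_one_trial(bp, wmode, trial, seed, duration_s, fs,
                      contact_threshold, response, schemes, filter_config,
                      eval_start_s, drive_freq_hz, drive_band_hz),
        error = function(e) {
          warning(sprintf("trial failed (%s, k=%g, trial %d): %s",
                          wmode, kk, trial, conditionMessage(e)),
                  call. = FALSE)
          NULL
        })
      if (is.null(out)) {
        n_failed <- n_failed + 1L
        out <- data.frame(whisking = wmode, k = kk,
                          scheme = c("raw", schemes), trial = trial,
                          snr_db = NA_real_, improvement_db = NA_real_,
                          n_contacts = NA_integer_, seed = seed)
      } else {
        out$whisking <- wmode
        out$k <- kk
        out$trial <- trial
        out$seed <- seed
      }
      rows[[length(rows) + 1L]] <- out
    }
  }
  if (n_failed > 0.1 * n_cells) {
    stop_invalid("scenario grid failed: %d of %d trials diverged",
                 n_failed, n_cells)
  }
  res <- do.call(rbind, rows)
  res <- res[, c("whisking", "k", "scheme", "trial", "snr_db",
                 "improvement_db", "n_contacts", "seed")]
  rownames(res) <- NULL
  class(res) <- c("scenario_grid", "data.frame")
  res
}

# Deterministic per-trial seed below 2^31, spread across cells.
trial_seed <- function(base_seed, i_whisk, i_k, trial) {
  (as.numeric(base_seed) + 1299709 * i_whisk + 15485863 * i_k +
     7919 * trial) %% 2147483629
}

run_one_trial <- function(bp, wmode, trial, seed, duration_s, fs,
                          contact_threshold, response, schemes,
                          filter_config, eval_start_s, drive_freq_hz,
                          drive_band_hz) {
  u <- if (wmode == "periodic") {
    make_sine(drive_freq_hz, sqrt(2), duration_s, fs)
  } else {
    make_bandpass_noise(drive_band_hz[1], drive_band_hz[2], duration_s, fs,
                        seed = seed)
  }
  schedule <- generate_contact_schedule(duration_s, fs, contact_threshold,
                                        seed = (seed + 1000003) %% 2147483629)
  r <- simulate_reafferent(bp, u)
  x <- render_exafferent(schedule, response, length(r$values))
  z <- compose_sensory(r, x)
  raw_snr <- compute_snr(z, schedule, eval_start_s = eval_start_s)$snr_db
  out <- data.frame(scheme = "raw", snr_db = raw_snr, improvement_db = 0,
                    n_contacts = length(schedule$times))
  for (scheme in schemes) {
    cfg <- filter_config
    cfg$mode <- scheme
    run <- run_novelty_scheme(u, z, cfg, snapshot_every_s = 0)
    s <- compute_snr(run$e, schedule, eval_start_s = eval_start_s)$snr_db
    out <- rbind(out, data.frame(scheme = scheme, snr_db = s,
                                 improvement_db = s - raw_snr,
                                 n_contacts = length(schedule$times)))
  }
  out
}

#' Aggregate scenario-grid trials
#'
#' Per-cell mean and standard deviation (n - 1 denominator) of the SNR
#' improvement across trials.
#'
#' @param grid A data frame from [run_scenario_grid()].
#' @param drop_raw Drop the raw-baseline rows (default `TRUE`).
#'
#' @return A data frame with columns `whisking`, `k`, `scheme`,
#'   `mean_improvement_db`, `sd_improvement_db`, `n_trials`.
#' @export
aggregate_scenarios <- function(grid, drop_raw = TRUE) {
  g <- as.data.frame(grid)
  if (drop_raw) g <- g[g$scheme != "raw", ]
  g <- g[!is.na(g$improvement_db), ]
  agg <- aggregate(improvement_db ~ whisking + k + scheme, data = g,
                   FUN = function(v) c(mean = mean(v), sd = sd(v),
                                       n = length(v)))
  out <- data.frame(whisking = agg$whisking, k = agg$k, scheme = agg$scheme,
                    mean_improvement_db = agg$improvement_db[, "mean"],
                    sd_improvement_db = agg$improvement_db[, "sd"],
                    n_trials = as.integer(agg$improvement_db[, "n"]))
  out[order(out$whisking, out$k, out$scheme), ]
}

#' Bar chart of scenario-grid results
#'
#' Mean SNR improvement per scheme, grouped by whisking mode, one panel
#' per bilinear coefficient; error bars show +/- one standard deviation
#' across trials. Uses base graphics.
#'
#' @param grid A data frame from [run_scenario_grid()].
#' @param ... Passed to [graphics::barplot()].
#'
#' @return The aggregate table, invisibly.
#' @importFrom graphics arrows barplot par title
#' @export
plot_scenario_grid <- function(grid, ...) {
  agg <- aggregate_scenarios(grid)
  ks <- sort(unique(agg$k))
  old <- par(mfrow = c(1, length(ks)))
  on.exit(par(old))
  for (kk in ks) {
    a <- agg[agg$k == kk, ]
    m <- tapply(a$mean_improvement_db, list(a$scheme, a$whisking), identity)
    s <- tapply(a$sd_improvement_db, list(a$scheme, a$whisking), identity)
    bp <- barplot(m, beside = TRUE, legend.text = rownames(m),
                  ylab = "SNR improvement (dB)",
                  ylim = c(0, max(m + s, na.rm = TRUE) * 1.15), ...)
    arrows(bp, m - s, bp, m + s, angle = 90, code = 3, length = 0.03)
    title(sprintf("k = %g", kk))
  }
  invisible(agg)
}
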