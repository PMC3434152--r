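#' Read and validate a run configuration
#'
#' Parses the structured plain-text (YAML) configuration used by the
#' command-line interface. Recognised sections and keys:
#'
#' * `plant`: either `a` and `b` (two coefficients each) or
#'   `natural_freq_hz`, `damping`, `dc_gain`; plus `k`, `sample_rate_hz`.
#' * `drive`: `mode` (`"periodic"`, `"stochastic"` or `"sawtooth"`),
#'   `freq_hz`, `amplitude`, `band_hz`, `duty_fraction`, `tau_s`.
#' * `contacts`: `threshold`, `response` (`freq_hz`, `duration_s`,
#'   `decay_s`, `amplitude_ratio`).
#' * `filter`: any [adaptive_filter_config()] argument.
#' * `experiment`: `duration_s`, `n_trials`, `eval_start_s`, `base_seed`,
#'   `k_values`, `schemes`.
#' * `output`: `dir`.
#'
#' Unknown sections or keys are rejected rather than ignored, so typos
#' cannot silently fall back to defaults.
#'
#' @param path Path to a YAML file.
#'
#' @return A list of class `run_config` with fully validated sections and
#'   constructed `plant` (a `linear_plant`), `k`, `filter_config` and
#'   `response` objects.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_invalid("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop_invalid("%s: config must be a YAML mapping", path)
  known <- c("plant", "drive", "contacts", "filter", "experiment", "output")
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    stop_invalid("%s: unknown config section(s): %s",
                 path, paste(extra, collapse = ", "))
  }

  take <- function(section, allowed) {
    s <- raw[[section]]
    if (is.null(s)) s <- list()
    bad <- setdiff(names(s), allowed)
    if (length(bad)) {
      stop_invalid("%s: unknown key(s) in section '%s': %s",
                   path, section, paste(bad, collapse = ", "))
    }
    s
  }
  p <- take("plant", c("a", "b", "natural_freq_hz", "damping", "dc_gain",
                       "k", "sample_rate_hz"))
  d <- take("drive", c("mode", "freq_hz", "amplitude", "band_hz",
                       "duty_fraction", "tau_s"))
  ct <- take("contacts", c("threshold", "response"))
  f <- take("filter", c("mode", "n_taps_per_input", "tap_spacing_s",
                        "learning_rate", "processing_delay_s",
                        "sensory_decorrelation_delay_s"))
  e <- take("experiment", c("duration_s", "n_trials", "eval_start_s",
                            "base_seed", "k_values", "schemes"))
  o <- take("output", "dir")

  fs <- p$sample_rate_hz %||% 200
  plant <- if (!is.null(p$a) || !is.null(p$b)) {
    if (is.null(p$a) || is.null(p$b)) {
      stop_invalid("%s: plant section needs both `a` and `b`", path)
    }
    linear_plant(unlist(p$a), unlist(p$b), fs)
  } else {
    default_plant(fs, p$natural_freq_hz %||% 20, p$damping %||% 1.0,
                  p$dc_gain %||% 1)
  }

  resp_cfg <- ct$response %||% list()
  bad <- setdiff(names(resp_cfg),
                 c("freq_hz", "duration_s", "decay_s", "amplitude_ratio"))
  if (length(bad)) {
    stop_invalid("%s: unknown key(s) in contacts$response: %s",
                 path, paste(bad, collapse = ", "))
  }

  cfg <- list(
    plant = plant,
    k = p$k %||% 0,
    drive = list(mode = match.arg(d$mode %||% "periodic",
                                  c("periodic", "stochastic", "sawtooth")),
                 freq_hz = d$freq_hz %||% 3,
                 amplitude = d$amplitude,
                 band_hz = unlist(d$band_hz %||% c(2, 4)),
                 duty_fraction = d$duty_fraction %||% 0.4,
                 tau_s = d$tau_s %||% 0.06),
    contacts = list(threshold = ct$threshold %||% 0.999,
                    response = resp_cfg),
    filter_config = adaptive_filter_config(
      mode = f$mode %||% "sensorimotor",
      n_taps_per_input = f$n_taps_per_input %||% 100,
      tap_spacing_s = f$tap_spacing_s %||% 0.005,
      learning_rate = f$learning_rate %||% 5e-4,
      processing_delay_s = f$processing_delay_s %||% 0.010,
      sensory_decorrelation_delay_s =
        f$sensory_decorrelation_delay_s %||% 0.100),
    experiment = list(duration_s = e$duration_s %||% 1000,
                      n_trials = e$n_trials %||% 20,
                      eval_start_s = e$eval_start_s,
                      base_seed = e$base_seed %||% 1,
                      k_values = unlist(e$k_values %||% c(0, 0.05)),
                      schemes = unlist(e$schemes %||%
                                         c("sensory", "motor",
                                           "sensorimotor"))),
    output_dir = o$dir %||% "whisknovelty-output",
    path = path)
  cfg$response <- do.call(default_contact_response,
                          c(list(plant = plant), resp_cfg))
  class(cfg) <- "run_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the configured whisking drive
#'
#' @param config A `run_config` from [read_run_config()].
#' @param duration_s Record duration; defaults to the experiment section.
#' @param seed Seed for the stochastic drive.
#' @return A [whisk_ts()] motor command.
#' @export
config_drive <- function(config, duration_s = NULL, seed = 1) {
  d <- config$drive
  fs <- config$plant$sample_rate_hz
  duration_s <- duration_s %||% config$experiment$duration_s
  switch(d$mode,
    # unit-RMS sine unless an amplitude is configured explicitly
    periodic = make_sine(d$freq_hz, d$amplitude %||% sqrt(2), duration_s,
                         fs),
    stochastic = make_bandpass_noise(d$band_hz[1], d$band_hz[2], duration_s,
                                     fs, seed),
    sawtooth = make_whisk_sawtooth(d$freq_hz, d$duty_fraction, d$tau_s,
                                   duration_s, fs,
                                   amplitude = d$amplitude %||% 1))
}
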