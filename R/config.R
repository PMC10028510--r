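#' Build a validated adaptation configuration
#'
#' All tunable constants of the personalization loop live in one flat
#' configuration object so that every rule model, the simulator and the
#' study runner draw their parameters from a single place.
#'
#' @param d0 Start difficulty of the first session (normalized game speed).
#' @param d_min,d_max Clamp bounds for difficulty.
#' @param session_length Session duration in seconds; heart rate is sampled
#'   at 1 Hz, so this is also the number of HR samples per session.
#' @param hr_max Heart-rate ceiling in beats per minute used by the packaged
#'   scenarios (an explicit override of the age-based formula).
#' @param window Number of most recent scores entering the trend estimate.
#' @param dead_band Half-width of the normalized-slope band classified as a
#'   constant trend.
#' @param eps Guard against division by zero when normalizing the slope.
#' @param step_constant Per-game difficulty increment for a constant trend.
#' @param k_score Gain mapping normalized slope to a difficulty delta.
#' @param max_step_offline Clip bound on the magnitude of any offline delta.
#' @param step_hr_offline Offline decrement applied when the session-mean
#'   heart rate exceeds the ceiling.
#' @param step_hr_realtime Immediate decrement applied while the smoothed
#'   in-session heart rate exceeds the ceiling.
#' @param t_eval Seconds between real-time evaluation instants.
#' @param ewma_alpha Smoothing weight of the exponentially weighted moving
#'   average applied to the streamed heart rate; the average is re-seeded
#'   with the first sample of each session.
#' @param rising_threshold Minimum increase (bpm) between consecutive
#'   session-mean heart rates for the "rising" flag.
#' @param age,sex,intensity Default player context for the heart-rate
#'   ceiling (a 25-year-old male exercising at full prescribed intensity).
#' @param resting_hr Default resting heart rate (bpm) of the simulated player.
#'
#' @return A list of class `adapt_config`.
#' @examples
#' cfg <- adapt_config()
#' cfg$d0
#' @export
adapt_config <- function(d0 = 0.8,
                         d_min = 0.2,
                         d_max = 1.6,
                         session_length = 60,
                         hr_max = 180,
                         window = 5,
                         dead_band = 0.05,
                         eps = 1e-9,
                         step_constant = 0.01,
                         k_score = 0.5,
                         max_step_offline = 0.08,
                         step_hr_offline = 0.05,
                         step_hr_realtime = 0.02,
                         t_eval = 5,
                         ewma_alpha = 0.3,
                         rising_threshold = 1,
                         age = 25,
                         sex = "male",
                         intensity = 1,
                         resting_hr = 62) {
  cfg <- list(
    d0 = d0, d_min = d_min, d_max = d_max,
    session_length = session_length, hr_max = hr_max,
    window = window, dead_band = dead_band, eps = eps,
    step_constant = step_constant, k_score = k_score,
    max_step_offline = max_step_offline,
    step_hr_offline = step_hr_offline,
    step_hr_realtime = step_hr_realtime,
    t_eval = t_eval, ewma_alpha = ewma_alpha,
    rising_threshold = rising_threshold,
    age = age, sex = sex, intensity = intensity,
    resting_hr = resting_hr
  )
  validate_config(cfg)
}

validate_config <- function(cfg) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in setdiff(names(cfg), "sex")) {
    if (!num1(cfg[[f]])) {
      abort(sprintf("config field `%s` must be a single finite number", f),
            class = "adaptloop_config_error")
    }
    cfg[[f]] <- as.numeric(cfg[[f]])  # JSON round-trip stability
  }
  if (!cfg$sex %in% c("male", "female", "other")) {
    abort("config field `sex` must be one of 'male', 'female', 'other'",
          class = "adaptloop_config_error")
  }
  if (cfg$d_min >= cfg$d_max) {
    abort("`d_min` must be strictly below `d_max`",
          class = "adaptloop_config_error")
  }
  if (cfg$d0 < cfg$d_min || cfg$d0 > cfg$d_max) {
    abort("`d0` must lie within [d_min, d_max]",
          class = "adaptloop_config_error")
  }
  checks <- list(
    session_length = cfg$session_length >= 1,
    hr_max = cfg$hr_max > 0,
    window = cfg$window >= 2,
    dead_band = cfg$dead_band >= 0,
    eps = cfg$eps > 0,
    step_constant = cfg$step_constant >= 0,
    k_score = cfg$k_score >= 0,
    max_step_offline = cfg$max_step_offline > 0,
    step_hr_offline = cfg$step_hr_offline >= 0 &&
      cfg$step_hr_offline <= cfg$max_step_offline,
    step_hr_realtime = cfg$step_hr_realtime >= 0,
    t_eval = cfg$t_eval >= 1,
    ewma_alpha = cfg$ewma_alpha > 0 && cfg$ewma_alpha <= 1,
    age = cfg$age > 0,
    intensity = cfg$intensity > 0 && cfg$intensity <= 1,
    resting_hr = cfg$resting_hr >= 30 && cfg$resting_hr <= 120
  )
  bad <- names(checks)[!vapply(checks, isTRUE, logical(1))]
  if (length(bad)) {
    abort(sprintf("config field(s) out of range: %s",
                  paste(bad, collapse = ", ")),
          class = "adaptloop_config_error")
  }
  structure(cfg, class = "adapt_config")
}

#' Load a run configuration from a JSON file
#'
#' Unknown keys are rejected so that typos in a configuration file surface
#' immediately; missing keys fall back to the documented defaults of
#' [adapt_config()]. An empty JSON object therefore yields the default
#' configuration (start difficulty 0.8, ceiling 180 bpm).
#'
#' @param path Path to a JSON file containing a single object.
#' @return An `adapt_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path),
          class = "adaptloop_config_error")
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw)) raw <- list()
  raw <- as.list(raw)
  known <- names(formals(adapt_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
          class = "adaptloop_config_error")
  }
  do.call(adapt_config, raw)
}

#' Serialize a configuration to JSON
#'
#' `load_config(write_config(cfg, path))` reproduces `cfg` exactly.
#'
#' @param cfg An `adapt_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "adapt_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.adapt_config <- function(x, ...) {
  cat("<adapt_config>\n")
  for (f in names(x)) cat(sprintf("  %-18s %s\n", f, format(x[[f]])))
  invisible(x)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
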