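#' Player profile for the simulated game
#'
#' @param age Age in years.
#' @param sex One of `"male"`, `"female"`, `"other"`.
#' @param skill Latent skill on the difficulty scale, >= 0; survival time is
#'   maximal when difficulty matches skill.
#' @param resting_hr Resting heart rate in bpm, within \[30, 120\].
#' @return A `player_profile`.
#' @export
player_profile <- function(age = 25, sex = c("male", "female", "other"),
                           skill = 0.8, resting_hr = 62) {
  sex <- match.arg(sex)
  stopifnot(is.numeric(age), age > 0, is.numeric(skill), skill >= 0)
  if (resting_hr < 30 || resting_hr > 120) {
    abort("`resting_hr` must lie in [30, 120] bpm",
          class = "adaptloop_domain_error")
  }
  structure(list(age = age, sex = sex, skill = skill,
                 resting_hr = resting_hr),
            class = "player_profile")
}

#' Current state of the game
#'
#' @param difficulty Normalized game speed within the clamp bounds.
#' @param session_index Session (game/level) counter, >= 1.
#' @param tick Seconds elapsed within the session.
#' @param config An [adapt_config()] fixing the bounds.
#' @return A `game_state`.
#' @export
game_state <- function(difficulty, session_index = 1L, tick = 0,
                       config = adapt_config()) {
  if (difficulty < config$d_min || difficulty > config$d_max) {
    abort(sprintf("difficulty %g outside [%g, %g]", difficulty,
                  config$d_min, config$d_max),
          class = "adaptloop_domain_error")
  }
  stopifnot(session_index >= 1, tick >= 0, tick <= config$session_length)
  structure(list(difficulty = difficulty,
                 session_index = as.integer(session_index), tick = tick),
            class = "game_state")
}

#' Apply an action command to the game state
#'
#' The single personalizable action of the game is its speed, identified
#' with the normalized difficulty. Requested values are clamped to
#' `[d_min, d_max]`; commands timed `next_session` apply at the session
#' boundary, `immediate` commands from the next tick.
#'
#' @param cmd An `action_command` (see [action_command()]).
#' @param state A `game_state`.
#' @param config An [adapt_config()].
#' @return The updated `game_state`.
#' @export
apply_action <- function(cmd, state, config = adapt_config()) {
  stopifnot(inherits(cmd, "action_command"), inherits(state, "game_state"))
  if (!identical(cmd$action_id, "speed")) {
    abort(sprintf("game exposes no action '%s'", cmd$action_id),
          class = "adaptloop_action_error")
  }
  requested <- if (!is.null(cmd$target)) cmd$target else state$difficulty + cmd$delta
  state$difficulty <- clip(requested, config$d_min, config$d_max)
  state
}

#' Play one scripted game session
#'
#' Replays a session whose score and per-tick heart rate come from a
#' scenario script. Without a real-time hook the in-session difficulty is
#' constant (offline adaptation only acts at session boundaries). With a
#' hook, the streamed heart rate is smoothed by an EWMA re-seeded with the
#' first sample of the session, and the hook is invoked at every evaluation
#' instant (every `t_eval` ticks) with the smoothed value; an
#' `action_command` returned by the hook takes effect from the next tick.
#'
#' @param session_index Game index, >= 1.
#' @param difficulty_in Difficulty at the start of the session.
#' @param score_script The session's score.
#' @param hr_script Per-tick bpm, length `session_length`, or `NULL` when
#'   the scenario carries no heart rate.
#' @param config An [adapt_config()].
#' @param realtime_hook Optional `function(smoothed_hr, tick)` returning an
#'   `action_command` or `NULL`.
#' @return A `session_record`: list with `session_index`, `score`,
#'   `hr_trace`, `smoothed_hr`, `difficulty_trace`, `end_difficulty`.
#' @export
play_session_scripted <- function(session_index, difficulty_in, score_script,
                                  hr_script = NULL,
                                  config = adapt_config(),
                                  realtime_hook = NULL) {
  len <- config$session_length
  if (!is.null(hr_script) && length(hr_script) != len) {
    abort(sprintf("hr script has %d samples; session length is %d",
                  length(hr_script), len),
          class = "adaptloop_script_error")
  }
  state <- game_state(difficulty_in, session_index, 0, config)
  difficulty_trace <- numeric(len)
  smoothed <- if (is.null(hr_script)) NULL else
    ewma(hr_script, config$ewma_alpha)
  for (t in seq_len(len)) {
    difficulty_trace[t] <- state$difficulty
    state$tick <- t
    if (!is.null(realtime_hook) && !is.null(hr_script) &&
        t %% config$t_eval == 0) {
      cmd <- realtime_hook(smoothed[t], t)
      if (!is.null(cmd)) state <- apply_action(cmd, state, config)
    }
  }
  structure(
    list(session_index = as.integer(session_index),
         score = score_script,
         hr_trace = hr_script,
         smoothed_hr = smoothed,
         difficulty_trace = difficulty_trace,
         end_difficulty = state$difficulty),
    class = "session_record"
  )
}

#' Play one session of the latent-skill player model
#'
#' A closed-loop stand-in for a human player of the Flappy-Bird-style
#' shoulder-rehabilitation game: score is a survival time that peaks when
#' the difficulty matches the player's latent skill and decays with the
#' challenge-skill mismatch, plus seeded noise; the heart rate rises from
#' the resting rate toward a plateau that increases with difficulty.
#' Fully reproducible given the seed.
#'
#' @param profile A [player_profile()].
#' @param difficulty_in Session difficulty.
#' @param rng_seed Integer seed; the only source of randomness.
#' @param config An [adapt_config()].
#' @return A `session_record`.
#' @export
play_session_latent <- function(profile, difficulty_in, rng_seed,
                                config = adapt_config()) {
  stopifnot(inherits(profile, "player_profile"))
  if (difficulty_in < config$d_min || difficulty_in > config$d_max) {
    abort("difficulty outside bounds", class = "adaptloop_domain_error")
  }
  len <- config$session_length
  withr::with_seed(rng_seed, {
    mismatch <- difficulty_in - profile$skill
    score <- max(0, 100 * exp(-(mismatch^2) / (2 * 0.3^2)) + stats::rnorm(1, 0, 3))
    plateau <- profile$resting_hr + 30 + 60 * difficulty_in
    t <- seq_len(len)
    hr <- plateau - (plateau - profile$resting_hr) * exp(-t / 20) +
      stats::rnorm(len, 0, 1.5)
    structure(
      list(session_index = 1L, score = score, hr_trace = hr,
           smoothed_hr = ewma(hr, config$ewma_alpha),
           difficulty_trace = rep(difficulty_in, len),
           end_difficulty = difficulty_in),
      class = "session_record"
    )
  })
}

#' Exponentially weighted moving average
#'
#' `s[1] = x[1]`; `s[t] = alpha * x[t] + (1 - alpha) * s[t - 1]`.
#'
#' @param x Numeric vector.
#' @param alpha Smoothing weight in (0, 1].
#' @return Numeric vector of smoothed values, same length as `x`.
#' @export
ewma <- function(x, alpha) {
  stopifnot(alpha > 0, alpha <= 1)
  if (length(x) == 0L) return(numeric(0))
  as.numeric(stats::filter(alpha * x, 1 - alpha,
                           method = "recursive", init = x[1]))
}
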