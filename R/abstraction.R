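#' Generic feature sample
#'
#' The generic, game-agnostic unit of observation entering the
#' personalization core: a tagged real value plus minimal metadata. The
#' value passes through unchanged (no normalization — normalizing would
#' require game knowledge the independent modules must not hold).
#'
#' @param feature_id Feature identifier (`"heart_rate"`, `"score"`, ...).
#' @param value Finite real; bpm for heart rate, score units for score.
#' @param session_index Game index, >= 1.
#' @param tick Seconds within the session; required when `phase` is
#'   `"in_session"`.
#' @param phase `"in_session"` or `"post_session"`.
#' @return A `feature_sample`.
#' @export
feature_sample <- function(feature_id, value, session_index,
                           tick = NULL,
                           phase = c("post_session", "in_session")) {
  phase <- match.arg(phase)
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
    abort("`value` must be a single finite number",
          class = "adaptloop_transform_error")
  }
  if (phase == "in_session" && is.null(tick)) {
    abort("in-session samples require a tick",
          class = "adaptloop_transform_error")
  }
  structure(list(feature_id = feature_id, value = value,
                 session_index = as.integer(session_index),
                 tick = tick, phase = phase),
            class = "feature_sample")
}

#' Transform a game-native observation into a generic feature sample
#'
#' The feature-transformer side of the game-specific boundary: wraps a raw,
#' tagged observation losslessly into a [feature_sample()]. Only tags
#' registered as features of the game are accepted.
#'
#' @param raw Named list with elements `feature` (tag), `value`, `session`
#'   and optionally `tick`.
#' @param features Character vector of feature tags the game exposes.
#' @return A `feature_sample` with the correct phase (`in_session` iff a
#'   tick is present).
#' @examples
#' transform_feature(list(feature = "score", value = 90, session = 3))
#' @export
transform_feature <- function(raw, features = c("heart_rate", "score")) {
  if (is.null(raw$feature) || !raw$feature %in% features) {
    abort(sprintf("unknown feature tag '%s'", raw$feature %||% "<missing>"),
          class = "adaptloop_transform_error")
  }
  feature_sample(
    feature_id = raw$feature, value = raw$value,
    session_index = raw$session, tick = raw$tick,
    phase = if (is.null(raw$tick)) "post_session" else "in_session"
  )
}

#' Resolve the context a feature's knowledge function requires
#'
#' The context locator knows which context maps to which feature: for the
#' score it returns the previous `window` scores (most recent last, fewer
#' when the history is short); for the heart rate the player's age, sex and
#' prescribed intensity. The returned bundle contains exactly the
#' parameters the knowledge entry declares.
#'
#' @param feature_id Feature identifier.
#' @param history Study state: a list with `scores` (numeric vector of
#'   completed-session scores, oldest first) and `profile` (a
#'   [player_profile()]).
#' @param kb A `knowledge_base`; the feature must be registered.
#' @param config An [adapt_config()] (supplies `window` and the default
#'   intensity).
#' @return A named list of class `context_bundle`.
#' @export
locate_context <- function(feature_id, history, kb = kb_default(config),
                           config = adapt_config()) {
  entry <- kb_lookup(kb, feature_id)
  ctx <- switch(
    entry$kind,
    score_trend = {
      if (is.null(history$scores)) {
        abort("history carries no scores for the score context",
              class = "adaptloop_context_error")
      }
      window <- entry$params$window %||% config$window
      list(previous_scores = utils::tail(history$scores, window))
    },
    hr_ceiling = {
      if (is.null(history$profile)) {
        abort("history carries no player profile for the heart-rate context",
              class = "adaptloop_context_error")
      }
      list(age = history$profile$age, sex = history$profile$sex,
           intensity = history$intensity %||% config$intensity)
    }
  )
  missing <- setdiff(entry$context_params, names(ctx))
  if (length(missing)) {
    abort(sprintf("missing history for context parameter(s): %s",
                  paste(missing, collapse = ", ")),
          class = "adaptloop_context_error")
  }
  structure(ctx[entry$context_params], class = "context_bundle")
}

#' Generic personalized value
#'
#' The output of a personalization model: a signed generic delta for one
#' action, tagged with its originating model and timing class. Offline
#' deltas are bounded by `max_step_offline`, immediate (real-time) deltas
#' by `step_hr_realtime`.
#'
#' @param action_id Action identifier (`"speed"`).
#' @param delta Signed generic change.
#' @param origin_model Identifier of the emitting model.
#' @param timing `"next_session"` or `"immediate"`.
#' @param config An [adapt_config()] fixing the per-timing step bounds.
#' @return A `personalized_value`.
#' @export
personalized_value <- function(action_id, delta, origin_model,
                               timing = c("next_session", "immediate"),
                               config = adapt_config()) {
  timing <- match.arg(timing)
  stopifnot(is.numeric(delta), length(delta) == 1L, is.finite(delta))
  max_step <- if (timing == "immediate") config$step_hr_realtime else
    config$max_step_offline
  if (abs(delta) > max_step + 1e-12) {
    abort(sprintf("|delta| = %g exceeds the %s step bound %g",
                  abs(delta), timing, max_step),
          class = "adaptloop_domain_error")
  }
  structure(list(action_id = action_id, delta = delta,
                 origin_model = origin_model, timing = timing),
            class = "personalized_value")
}

#' Game-specific action command
#'
#' @param action_id Action identifier (`"speed"`).
#' @param target Absolute difficulty, or `NULL`.
#' @param delta Signed difficulty change, or `NULL`. Exactly one of
#'   `target`/`delta` must be set.
#' @param timing `"next_session"` or `"immediate"`.
#' @return An `action_command`.
#' @export
action_command <- function(action_id, target = NULL, delta = NULL,
                           timing = c("next_session", "immediate")) {
  timing <- match.arg(timing)
  if (is.null(target) == is.null(delta)) {
    abort("exactly one of `target`/`delta` must be set",
          class = "adaptloop_action_error")
  }
  structure(list(action_id = action_id, target = target, delta = delta,
                 timing = timing),
            class = "action_command")
}

#' Transform a generic personalized value into a game command
#'
#' The action-transformer (speed transformer) side of the boundary:
#' performs the reverse of feature abstraction, mapping the generic delta
#' one-to-one onto a difficulty delta of the `"speed"` action. Timing is
#' `immediate` iff the value originated from a real-time model.
#'
#' @param pv A [personalized_value()].
#' @return An `action_command`.
#' @export
transform_action <- function(pv) {
  stopifnot(inherits(pv, "personalized_value"))
  if (!identical(pv$action_id, "speed")) {
    abort(sprintf("unknown action '%s'", pv$action_id),
          class = "adaptloop_action_error")
  }
  action_command("speed", delta = pv$delta, timing = pv$timing)
}
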