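#' Interpret a feature sample into a processed value
#'
#' The interpreter is the first game-independent stage: it combines a
#' generic feature sample with the knowledge entry for that feature and the
#' located context, and emits a processed value — the game-agnostic
#' "personalization need". The sign convention, used everywhere in the
#' package, is: positive need = reduce challenge, negative need = increase
#' challenge.
#'
#' For the heart rate, `need = clip((value - hr_max) / hr_max, -1, 1)`,
#' `over_limit = value > hr_max`, and `rising` is true when the current
#' session-mean heart rate exceeds the previous one by more than
#' `rising_threshold` bpm (false when only one mean is known). For the
#' score, the trend verdict over the previous scores plus the new value
#' gives `need = -clip(norm_slope, -1, 1)`.
#'
#' @param sample A [feature_sample()].
#' @param entry The matching `knowledge_entry`.
#' @param ctx The matching `context_bundle` — must contain exactly the
#'   parameters the entry declares.
#' @param config An [adapt_config()].
#' @param prev_mean Previous session-mean heart rate in bpm, or `NULL`
#'   (loop state carried by the study runner, not part of the context).
#' @param cur_mean Current session-mean heart rate; defaults to the sample
#'   value (which is the session mean for post-session samples).
#' @return A `processed_value`: list with `feature_id`, `need`,
#'   `over_limit`, `rising`, `trend` (one-row tibble or `NULL`),
#'   `session_index`, `phase`.
#' @export
interpret <- function(sample, entry, ctx, config = adapt_config(),
                      prev_mean = NULL, cur_mean = NULL) {
  stopifnot(inherits(sample, "feature_sample"),
            inherits(entry, "knowledge_entry"))
  if (!setequal(names(ctx), entry$context_params)) {
    abort(sprintf(
      "context {%s} does not match the declared parameters {%s}",
      paste(names(ctx), collapse = ", "),
      paste(entry$context_params, collapse = ", ")),
      class = "adaptloop_interpretation_error")
  }
  if (entry$kind == "hr_ceiling") {
    hr_max <- entry$params$override_hr_max %||%
      eval_hr_max(ctx$age, ctx$sex, ctx$intensity)
    need <- clip((sample$value - hr_max) / hr_max, -1, 1)
    cur <- cur_mean %||% sample$value
    rising <- !is.null(prev_mean) && (cur - prev_mean) > config$rising_threshold
    pv <- list(feature_id = sample$feature_id, need = need,
               over_limit = sample$value > hr_max, rising = rising,
               trend = NULL, hr_max = hr_max,
               session_index = sample$session_index, phase = sample$phase)
  } else {
    trend <- eval_score_trend(
      c(ctx$previous_scores, sample$value),
      window = entry$params$window %||% config$window,
      dead_band = entry$params$dead_band %||% config$dead_band,
      eps = config$eps)
    pv <- list(feature_id = sample$feature_id,
               need = -clip(trend$norm_slope, -1, 1),
               over_limit = FALSE, rising = FALSE, trend = trend,
               hr_max = NA_real_,
               session_index = sample$session_index, phase = sample$phase)
  }
  structure(pv, class = "processed_value")
}

#' Default model registry
#'
#' The three packaged rule models: an offline model over the processed
#' score alone, an offline model over processed score and heart rate, and a
#' real-time model over the same inputs. Several models may be registered
#' simultaneously; the study runner activates exactly one per mode.
#'
#' @param active Character vector of model ids to activate.
#' @return A tibble with columns `model_id`, `inputs` (list-column of
#'   feature ids), `mode` and `active`.
#' @export
default_models <- function(active = c("offline_score_hr", "realtime_score_hr")) {
  tibble::tibble(
    model_id = c("offline_score", "offline_score_hr", "realtime_score_hr"),
    inputs = list("score", c("score", "heart_rate"), c("score", "heart_rate")),
    mode = c("offline", "offline", "realtime"),
    active = c("offline_score", "offline_score_hr", "realtime_score_hr") %in% active
  )
}

#' Route a processed value to the responsible model
#'
#' The model locator: a processed value produced post-session is routed to
#' an active offline model, an in-session value to an active real-time
#' model; among those, the model must list the value's feature among its
#' inputs. Exactly one active model may match.
#'
#' @param pv A `processed_value`.
#' @param registry A model registry tibble (see [default_models()]).
#' @return The matching `model_id`.
#' @export
route_model <- function(pv, registry = default_models()) {
  stopifnot(inherits(pv, "processed_value"), nrow(registry) > 0)
  want_mode <- if (pv$phase == "in_session") "realtime" else "offline"
  hit <- registry$active & registry$mode == want_mode &
    purrr::map_lgl(registry$inputs, ~ pv$feature_id %in% .x)
  if (sum(hit) == 0L) {
    abort(sprintf("no active %s model accepts feature '%s'",
                  want_mode, pv$feature_id),
          class = "adaptloop_routing_error")
  }
  if (sum(hit) > 1L) {
    abort(sprintf("ambiguous routing: %s",
                  paste(registry$model_id[hit], collapse = ", ")),
          class = "adaptloop_configuration_error")
  }
  registry$model_id[hit]
}

#' Offline model over the processed score
#'
#' Rule model answering the score trend alone: a constant trend earns a
#' slow fixed increase in difficulty; upward and downward trends earn a
#' delta proportional to the normalized slope (gain `k_score`), clipped to
#' `max_step_offline`, so a sustained improvement raises difficulty
#' markedly and a sustained decline lowers it.
#'
#' @param trend A trend verdict from [eval_score_trend()], or `NULL` (fewer
#'   than two scores yet).
#' @param config An [adapt_config()].
#' @return A [personalized_value()] timed `next_session`, or `NULL`.
#' @export
model_offline_score <- function(trend, config = adapt_config()) {
  if (is.null(trend)) return(NULL)
  delta <- if (trend$cls == "constant") {
    config$step_constant
  } else {
    clip(config$k_score * trend$norm_slope,
         -config$max_step_offline, config$max_step_offline)
  }
  personalized_value("speed", delta, "offline_score",
                     timing = "next_session", config = config)
}

#' Offline model over processed score and heart rate
#'
#' The heart rate takes precedence over the score: a session-mean heart
#' rate over the ceiling forces a fixed decrease; a rising sub-ceiling
#' heart rate holds the difficulty; otherwise the score model decides.
#'
#' @param trend A trend verdict, or `NULL`.
#' @param hr A post-session `processed_value` for the heart rate (session
#'   mean based), or `NULL` when the scenario carries no heart rate.
#' @param config An [adapt_config()].
#' @return A [personalized_value()] timed `next_session`, or `NULL`.
#' @export
model_offline_score_hr <- function(trend, hr, config = adapt_config()) {
  if (!is.null(hr)) {
    if (hr$over_limit) {
      return(personalized_value("speed", -config$step_hr_offline,
                                "offline_score_hr",
                                timing = "next_session", config = config))
    }
    if (hr$rising) {
      return(personalized_value("speed", 0, "offline_score_hr",
                                timing = "next_session", config = config))
    }
  }
  pv <- model_offline_score(trend, config)
  if (is.null(pv)) return(NULL)
  personalized_value("speed", pv$delta, "offline_score_hr",
                     timing = "next_session", config = config)
}

#' Real-time model: per-instant heart-rate rule
#'
#' Called at each evaluation instant with the EWMA-smoothed heart rate:
#' while the smoothed value exceeds the ceiling, an immediate fixed
#' decrement is emitted; otherwise no command. The session-end score
#' handling (no score adjustment in sessions that saw an immediate command
#' or a rising heart rate, else the offline score model) is composed by the
#' study runner.
#'
#' @param smoothed_hr Smoothed heart rate in bpm.
#' @param hr_max Ceiling in bpm.
#' @param config An [adapt_config()].
#' @return A [personalized_value()] timed `immediate`, or `NULL`.
#' @export
model_realtime_score_hr <- function(smoothed_hr, hr_max,
                                    config = adapt_config()) {
  if (smoothed_hr > hr_max) {
    personalized_value("speed", -config$step_hr_realtime,
                       "realtime_score_hr", timing = "immediate",
                       config = config)
  } else {
    NULL
  }
}

#' Run the post-session personalization chain on a stream of samples
#'
#' Composes locate-context, interpret, route and the offline rule models
#' for the feature samples a game emits after one session. This is the
#' whole game-independent path: any game (or stub) producing identical
#' samples receives identical commands.
#'
#' @param samples List of post-session [feature_sample()]s (score and
#'   optionally heart rate) from one session.
#' @param history Study state passed to [locate_context()]; additionally
#'   `prev_mean` (previous session-mean heart rate, or `NULL`).
#' @param kb A `knowledge_base`.
#' @param registry A model registry with one active offline model.
#' @param config An [adapt_config()].
#' @return A [personalized_value()] or `NULL`, with attribute `"processed"`
#'   holding the processed values by feature.
#' @export
personalize_post_session <- function(samples, history, kb = kb_default(config),
                                     registry = default_models(),
                                     config = adapt_config()) {
  processed <- list()
  for (s in samples) {
    entry <- kb_lookup(kb, s$feature_id)
    ctx <- locate_context(s$feature_id, history, kb, config)
    if (entry$kind == "score_trend" &&
        length(c(ctx$previous_scores, s$value)) < 2L) {
      next  # first session: no trend yet
    }
    processed[[s$feature_id]] <-
      interpret(s, entry, ctx, config, prev_mean = history$prev_mean)
  }
  if (length(processed) == 0L) return(NULL)
  model_id <- route_model(processed[[1L]], registry)
  trend <- processed$score$trend
  pv <- switch(model_id,
               offline_score = model_offline_score(trend, config),
               offline_score_hr = model_offline_score_hr(
                 trend, processed$heart_rate, config),
               abort(sprintf("model '%s' is not an offline rule model",
                             model_id),
                     class = "adaptloop_routing_error"))
  if (!is.null(pv)) attr(pv, "processed") <- processed
  pv
}
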