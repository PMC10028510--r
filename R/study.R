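#' Run the offline personalization loop over a scenario
#'
#' Each game is played at a difficulty fixed before it starts (the first at
#' `d0`); after each game the session's feature samples — the score and,
#' when the scenario scripts it, the session-mean heart rate — run through
#' the abstraction, interpretation and model stages, and the resulting
#' command adapts the next game.
#'
#' @param scn A [make_scenario()] scenario.
#' @param model_id Active offline model: `"offline_score"` or
#'   `"offline_score_hr"`.
#' @param config An [adapt_config()].
#' @param kb A `knowledge_base`.
#' @param profile A [player_profile()].
#' @return A `study_result`: list with `mode`, `trace` (tibble `game, mode,
#'   score, mean_hr, end_difficulty`), `commands` (tibble `game, model_id,
#'   delta, timing`), `metrics` (list), `in_session` (tibble `game, tick,
#'   difficulty`).
#' @export
run_offline_loop <- function(scn, model_id = "offline_score_hr",
                             config = adapt_config(),
                             kb = kb_default(config),
                             profile = player_profile(
                               config$age, config$sex,
                               resting_hr = config$resting_hr)) {
  stopifnot(inherits(scn, "scenario"))
  registry <- default_models(active = model_id)
  spec <- registry[registry$model_id == model_id, ]
  if (nrow(spec) == 0L || spec$mode != "offline") {
    abort(sprintf("'%s' is not a registered offline model", model_id),
          class = "adaptloop_mode_error")
  }
  run_loop(scn, model_id, registry, spec, config, kb, profile,
           realtime = FALSE)
}

#' Run the real-time personalization loop over a scenario
#'
#' Within each session the scripted heart rate is streamed at 1 Hz, EWMA
#' smoothed, and evaluated every `t_eval` seconds; immediate decrements
#' apply from the next tick while the smoothed heart rate exceeds the
#' ceiling. At session end, sessions that saw an immediate command or a
#' rising heart rate receive no score adjustment; otherwise the offline
#' score model applies. Difficulty carries over between sessions.
#'
#' @inheritParams run_offline_loop
#' @param model_id Active real-time model (`"realtime_score_hr"`).
#' @return A `study_result`.
#' @export
run_realtime_loop <- function(scn, model_id = "realtime_score_hr",
                              config = adapt_config(),
                              kb = kb_default(config),
                              profile = player_profile(
                                config$age, config$sex,
                                resting_hr = config$resting_hr)) {
  stopifnot(inherits(scn, "scenario"))
  if (is.null(scn$hr)) {
    abort("real-time adaptation needs per-tick heart-rate scripts",
          class = "adaptloop_mode_error")
  }
  registry <- default_models(active = c(model_id, "offline_score"))
  spec <- registry[registry$model_id == model_id, ]
  if (nrow(spec) == 0L || spec$mode != "realtime") {
    abort(sprintf("'%s' is not a registered real-time model", model_id),
          class = "adaptloop_mode_error")
  }
  run_loop(scn, model_id, registry, spec, config, kb, profile,
           realtime = TRUE)
}

# Shared loop body. In offline mode commands apply at session boundaries
# only; in real-time mode a hook lowers difficulty mid-session and the
# session-end score rule applies when no immediate command fired and the
# heart rate is not rising.
run_loop <- function(scn, model_id, registry, spec, config, kb, profile,
                     realtime) {
  n <- scn$n_games
  trace <- vector("list", n)
  in_session <- vector("list", n)
  commands <- list()
  scores_seen <- numeric(0)
  prev_mean <- NULL
  d <- config$d0
  hr_entry <- if ("heart_rate" %in% spec$inputs[[1]])
    kb_lookup(kb, "heart_rate") else NULL

  for (g in seq_len(n)) {
    hr_script <- scenario_hr_script(scn, g)
    immediate_cmds <- 0L
    hook <- NULL
    if (realtime) {
      hr_max <- hr_entry$params$override_hr_max %||%
        eval_hr_max(profile$age, profile$sex, config$intensity)
      hook <- function(smoothed, tick) {
        pv <- model_realtime_score_hr(smoothed, hr_max, config)
        if (is.null(pv)) return(NULL)
        immediate_cmds <<- immediate_cmds + 1L
        commands[[length(commands) + 1L]] <<- tibble::tibble(
          game = g, tick = tick, model_id = pv$origin_model,
          delta = pv$delta, timing = pv$timing)
        transform_action(pv)
      }
    }
    rec <- play_session_scripted(g, d, scn$scores$score[g], hr_script,
                                 config, realtime_hook = hook)
    mean_hr <- if (is.null(hr_script)) NA_real_ else mean(hr_script)
    rising <- !is.null(prev_mean) && !is.na(mean_hr) &&
      (mean_hr - prev_mean) > config$rising_threshold

    # post-session personalization deciding the next session's difficulty
    delta <- 0
    if (realtime) {
      if (immediate_cmds == 0L && !rising) {
        pv <- personalize_post_session(
          list(transform_feature(list(feature = "score", value = rec$score,
                                      session = g))),
          history = list(scores = scores_seen, profile = profile),
          kb = kb, registry = default_models(active = "offline_score"),
          config = config)
        if (!is.null(pv)) {
          delta <- pv$delta
          commands[[length(commands) + 1L]] <- tibble::tibble(
            game = g, tick = NA_integer_, model_id = pv$origin_model,
            delta = pv$delta, timing = pv$timing)
        }
      }
    } else {
      samples <- list(transform_feature(list(feature = "score",
                                             value = rec$score, session = g)))
      if (!is.null(hr_entry) && !is.na(mean_hr)) {
        samples <- c(samples, list(transform_feature(
          list(feature = "heart_rate", value = mean_hr, session = g))))
      }
      pv <- personalize_post_session(
        samples,
        history = list(scores = scores_seen, profile = profile,
                       prev_mean = prev_mean),
        kb = kb, registry = registry, config = config)
      if (!is.null(pv)) {
        delta <- pv$delta
        commands[[length(commands) + 1L]] <- tibble::tibble(
          game = g, tick = NA_integer_, model_id = pv$origin_model,
          delta = pv$delta, timing = pv$timing)
      }
    }

    trace[[g]] <- tibble::tibble(
      game = g, mode = if (realtime) "realtime" else "offline",
      score = rec$score, mean_hr = mean_hr,
      end_difficulty = rec$end_difficulty)
    in_session[[g]] <- tibble::tibble(
      game = g, tick = seq_len(config$session_length),
      difficulty = rec$difficulty_trace)
    scores_seen <- c(scores_seen, rec$score)
    if (!is.na(mean_hr)) prev_mean <- mean_hr
    d <- clip(rec$end_difficulty + delta, config$d_min, config$d_max)
  }

  trace <- dplyr::bind_rows(trace)
  result <- structure(
    list(mode = if (realtime) "realtime" else "offline",
         model_id = model_id,
         trace = trace,
         commands = dplyr::bind_rows(commands),
         in_session = dplyr::bind_rows(in_session),
         metrics = list()),
    class = "study_result"
  )
  result$metrics <- if (n > 0) compute_metrics(result) else list()
  result
}

#' Timing metrics of a difficulty trace
#'
#' Derives from a per-game end-of-session difficulty trace:
#' `first_decrease_game`, the first game whose difficulty is strictly below
#' the previous game's (`NA` if none); `argmin_game`, the earliest game
#' attaining the trace minimum; `min_difficulty`; and, when a reference
#' minimum is given (typically the offline run's), `reach_game`, the first
#' game at or below that reference.
#'
#' @param result A `study_result`, or a numeric difficulty trace.
#' @param reference_min Optional reference difficulty.
#' @return A named list of metrics.
#' @export
compute_metrics <- function(result, reference_min = NULL) {
  x <- if (inherits(result, "study_result")) {
    result$trace$end_difficulty
  } else {
    as.numeric(result)
  }
  if (length(x) == 0L) {
    abort("cannot compute metrics of an empty trace",
          class = "adaptloop_metrics_error")
  }
  dec <- which(diff(x) < 0)
  metrics <- list(
    first_decrease_game = if (length(dec)) dec[1] + 1L else NA_integer_,
    argmin_game = which.min(x),
    min_difficulty = min(x)
  )
  if (!is.null(reference_min)) {
    reach <- which(x <= reference_min)
    metrics$reach_game <- if (length(reach)) reach[1] else NA_integer_
  }
  metrics
}

#' Run a scenario in one or both modes
#'
#' Convenience wrapper running [run_offline_loop()] and/or
#' [run_realtime_loop()] on one scenario and, when both run, adding the
#' cross-mode timing metric (`reach_game`: the first game at which the
#' real-time trace is at or below the offline run's minimum).
#'
#' @param scn A scenario.
#' @param modes Subset of `c("offline", "realtime")`.
#' @param config An [adapt_config()].
#' @param offline_model Offline model id.
#' @return A named list of `study_result`s, class `study_set`.
#' @export
run_study <- function(scn, modes = c("offline", "realtime"),
                      config = adapt_config(),
                      offline_model = "offline_score_hr") {
  modes <- match.arg(modes, several.ok = TRUE)
  out <- list()
  if ("offline" %in% modes) {
    out$offline <- run_offline_loop(scn, offline_model, config)
  }
  if ("realtime" %in% modes) {
    out$realtime <- run_realtime_loop(scn, config = config)
  }
  if (!is.null(out$offline) && !is.null(out$realtime)) {
    out$realtime$metrics <- compute_metrics(
      out$realtime, reference_min = out$offline$metrics$min_difficulty)
  }
  structure(out, class = "study_set")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result: %s mode, model %s, %d games>\n",
              x$mode, x$model_id, nrow(x$trace)))
  m <- x$metrics
  if (length(m)) {
    cat(sprintf("  first decrease: game %s | argmin: game %s | min: %.3f\n",
                format(m$first_decrease_game), format(m$argmin_game),
                m$min_difficulty))
  }
  invisible(x)
}

#' @export
print.study_set <- function(x, ...) {
  for (r in x) print(r)
  invisible(x)
}

#' Tidy and summarize study results
#'
#' `tidy()` returns the per-game trace tibble (`game, mode, score, mean_hr,
#' end_difficulty`); `glance()` a one-row tibble of the timing metrics.
#'
#' @param x A `study_result` or `study_set`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.study_result <- function(x, ...) x$trace

#' @rdname tidy.study_result
#' @export
glance.study_result <- function(x, ...) {
  tibble::tibble(
    mode = x$mode, model_id = x$model_id, n_games = nrow(x$trace),
    first_decrease_game = as.integer(x$metrics$first_decrease_game),
    argmin_game = as.integer(x$metrics$argmin_game),
    min_difficulty = x$metrics$min_difficulty,
    reach_game = as.integer(x$metrics$reach_game %||% NA_integer_)
  )
}

#' @rdname tidy.study_result
#' @export
tidy.study_set <- function(x, ...) {
  dplyr::bind_rows(lapply(unclass(x), tidy))
}

#' @rdname tidy.study_result
#' @export
glance.study_set <- function(x, ...) {
  dplyr::bind_rows(lapply(unclass(x), glance))
}
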