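#' Create an empty knowledge base
#'
#' The knowledge base holds the domain expert's formalized knowledge: one
#' entry per personalization feature, naming the knowledge function kind and
#' the context parameters it requires. The interpreter consults it to give
#' meaning to incoming feature samples.
#'
#' @return An object of class `knowledge_base`.
#' @seealso [kb_register()], [kb_lookup()], [kb_default()]
#' @export
knowledge_base <- function() {
  structure(list(entries = list()), class = "knowledge_base")
}

#' Register a knowledge entry
#'
#' @param kb A `knowledge_base`.
#' @param feature_id Unique feature identifier (e.g. `"heart_rate"`).
#' @param kind Knowledge-function kind: `"hr_ceiling"` (a personalized
#'   heart-rate ceiling) or `"score_trend"` (a sliding-window trend
#'   estimate over recent scores).
#' @param context_params Character vector naming the context parameters the
#'   knowledge function requires; must be non-empty.
#' @param params Named list of knowledge-function parameters (e.g.
#'   `override_hr_max`, `window`, `dead_band`).
#' @return The updated `knowledge_base` (registration is functional).
#' @examples
#' kb <- knowledge_base() |>
#'   kb_register("heart_rate", "hr_ceiling", c("age", "sex", "intensity"),
#'               params = list(override_hr_max = 180))
#' kb_lookup(kb, "heart_rate")$kind
#' @export
kb_register <- function(kb, feature_id, kind = c("hr_ceiling", "score_trend"),
                        context_params, params = list()) {
  stopifnot(inherits(kb, "knowledge_base"))
  kind <- match.arg(kind)
  if (!is.character(feature_id) || length(feature_id) != 1L || !nzchar(feature_id)) {
    abort("`feature_id` must be a single non-empty string",
          class = "adaptloop_registration_error")
  }
  if (feature_id %in% names(kb$entries)) {
    abort(sprintf("feature '%s' is already registered", feature_id),
          class = "adaptloop_registration_error")
  }
  if (!is.character(context_params) || length(context_params) == 0L) {
    abort("`context_params` must be a non-empty character vector",
          class = "adaptloop_registration_error")
  }
  entry <- structure(
    list(feature_id = feature_id, kind = kind,
         context_params = unique(context_params), params = params),
    class = "knowledge_entry"
  )
  kb$entries[[feature_id]] <- entry
  kb
}

#' Look up a knowledge entry by feature
#'
#' @param kb A `knowledge_base`.
#' @param feature_id Feature identifier.
#' @return The matching `knowledge_entry`.
#' @export
kb_lookup <- function(kb, feature_id) {
  stopifnot(inherits(kb, "knowledge_base"))
  entry <- kb$entries[[feature_id]]
  if (is.null(entry)) {
    abort(sprintf("no knowledge registered for feature '%s'", feature_id),
          class = "adaptloop_lookup_error")
  }
  entry
}

#' Default knowledge base of the shoulder-rehabilitation game
#'
#' Registers the two features the proof-of-concept game personalizes on:
#' the heart rate (ceiling function over age, sex and exercise intensity,
#' pinned to an explicit 180 bpm override in the packaged scenarios) and
#' the game score (trend over the previous `window` scores).
#'
#' @param config An [adapt_config()].
#' @return A populated `knowledge_base`.
#' @export
kb_default <- function(config = adapt_config()) {
  knowledge_base() |>
    kb_register("heart_rate", "hr_ceiling",
                context_params = c("age", "sex", "intensity"),
                params = list(override_hr_max = config$hr_max)) |>
    kb_register("score", "score_trend",
                context_params = "previous_scores",
                params = list(window = config$window,
                              dead_band = config$dead_band))
}

#' Personalized heart-rate ceiling
#'
#' Returns the highest accepted heart rate for a player. Without an
#' override the ceiling follows the age-predicted maximum scaled by the
#' prescribed exercise intensity, `(220 - age) * intensity`; a supplied
#' override wins unconditionally (the packaged scenarios pin 180 bpm).
#'
#' @param age Age in years, > 0.
#' @param sex One of `"male"`, `"female"`, `"other"`. Recorded as context;
#'   the default formula is sex-independent.
#' @param intensity Prescribed intensity in (0, 1].
#' @param override Optional explicit ceiling in bpm.
#' @return The ceiling in beats per minute (a single number).
#' @examples
#' eval_hr_max(25, "male", 1, override = 180)
#' eval_hr_max(20, "male", 1)   # 200
#' @export
eval_hr_max <- function(age, sex = c("male", "female", "other"),
                        intensity = 1, override = NULL) {
  sex <- match.arg(sex)
  if (!is.numeric(age) || length(age) != 1L || !is.finite(age) || age <= 0) {
    abort("`age` must be a single positive number",
          class = "adaptloop_domain_error")
  }
  if (!is.numeric(intensity) || length(intensity) != 1L ||
      !is.finite(intensity) || intensity <= 0 || intensity > 1) {
    abort("`intensity` must lie in (0, 1]", class = "adaptloop_domain_error")
  }
  if (!is.null(override)) {
    if (!is.numeric(override) || length(override) != 1L || override <= 0) {
      abort("`override` must be a single positive number",
            class = "adaptloop_domain_error")
    }
    return(as.numeric(override))
  }
  (220 - age) * intensity
}

#' Sliding-window score trend
#'
#' Ordinary-least-squares slope of score against game index over the last
#' `min(window, length(scores))` scores, normalized by the window mean so
#' that the classification is invariant to the score scale. Slopes whose
#' normalized value lies within the dead-band classify as `constant`.
#'
#' @param scores Numeric vector of scores, oldest first; at least 2 values.
#' @param window Window size, >= 2.
#' @param dead_band Classification dead-band on the normalized slope.
#' @param eps Floor for the normalizing mean.
#' @return A one-row tibble (the trend verdict) with columns `slope`
#'   (score units per game), `norm_slope` (dimensionless) and `cls`
#'   (`"upward"`, `"constant"` or `"downward"`).
#' @examples
#' eval_score_trend(c(10, 12, 14, 16, 18))   # upward, slope 2
#' @export
eval_score_trend <- function(scores, window = 5, dead_band = 0.05, eps = 1e-9) {
  if (!is.numeric(scores) || length(scores) < 2L) {
    abort("trend estimation needs at least 2 scores",
          class = "adaptloop_insufficient_data_error")
  }
  if (window < 2) {
    abort("`window` must be >= 2", class = "adaptloop_domain_error")
  }
  y <- utils::tail(scores, min(window, length(scores)))
  x <- seq_along(y) - 1
  mx <- mean(x)
  my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  norm_slope <- slope / max(my, eps)
  cls <- if (norm_slope > dead_band) {
    "upward"
  } else if (norm_slope < -dead_band) {
    "downward"
  } else {
    "constant"
  }
  tibble::tibble(slope = slope, norm_slope = norm_slope, cls = cls)
}
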