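#' Deterministic study scenarios
#'
#' Builds the packaged 30-game scenarios used throughout the simulation
#' study. The three score-only scenarios realize the qualitative shapes the
#' adaptation rules must respond to — a noisy-but-constant score, a
#' sustained improvement, a sustained decline — and the rising-heart-rate
#' scenario combines a constant score of 90 with a per-game mean heart rate
#' of `128 + 2 g` bpm that first exceeds the 180 bpm ceiling instantaneously
#' in game 26 and in session mean (182 bpm) in game 27.
#'
#' All generators are seed-free and bit-deterministic.
#'
#' @param name Scenario name: `"constant_score"`, `"upward_score"`,
#'   `"downward_score"` or `"rising_hr"`.
#' @param config An [adapt_config()]; fixes the session length (hence the
#'   number of 1 Hz heart-rate samples per session) and the ceiling.
#' @return An object of class `scenario`: a list with `name`, `n_games`,
#'   `scores` (tibble `game, score`), `hr` (tibble `game, tick, bpm`, or
#'   `NULL` for score-only scenarios), `hr_max` and `session_length`.
#' @examples
#' scn <- make_scenario("rising_hr")
#' dplyr::filter(scn$hr, game == 27) |> dplyr::summarise(mean(bpm))
#' @export
make_scenario <- function(name = c("constant_score", "upward_score",
                                   "downward_score", "rising_hr"),
                          config = adapt_config()) {
  name <- tryCatch(match.arg(name),
                   error = function(e) abort(
                     sprintf("unknown scenario '%s'", name[1]),
                     class = "adaptloop_scenario_error"))
  n_games <- 30L
  scores <- switch(
    name,
    # 1-9 alternate high/low, 10-13 decline, 14 jumps, 15-30 constant
    constant_score = c(rep(c(70, 50), length.out = 9),
                       60, 52, 44, 38, 90, rep(90, 16)),
    # 1-13 constant, 14-15 dip, then a steady +7/game improvement
    upward_score = c(rep(60, 13), 50, 48, 55 + 7 * (0:14)),
    # 1-15 constant, 16-26 steady -5/game decline, 27-30 recovery plateau
    downward_score = c(rep(60, 15), 55 - 5 * (0:10), rep(40, 4)),
    rising_hr = rep(90, n_games)
  )
  hr <- NULL
  if (name == "rising_hr") {
    len <- config$session_length
    hr <- tidyr::expand_grid(game = seq_len(n_games), tick = seq_len(len)) |>
      dplyr::mutate(
        bpm = 128 + 2 * .data$game - 2 + 4 * (.data$tick - 1) / (len - 1)
      )
  }
  structure(
    list(name = name, n_games = n_games,
         scores = tibble::tibble(game = seq_len(n_games), score = scores),
         hr = hr, hr_max = config$hr_max,
         session_length = config$session_length),
    class = "scenario"
  )
}

#' Per-tick heart-rate script of one session
#'
#' @param scn A `scenario`.
#' @param game Game index.
#' @return Numeric vector of bpm (length `session_length`), or `NULL` if the
#'   scenario carries no heart-rate scripts.
#' @export
scenario_hr_script <- function(scn, game) {
  stopifnot(inherits(scn, "scenario"))
  if (is.null(scn$hr)) return(NULL)
  scn$hr$bpm[scn$hr$game == game]
}

#' Write a scenario to plain-text files
#'
#' Writes `scores.csv` (`game,score`), `hr.csv` (`game,tick,bpm`, only when
#' present) and `meta.json` into `dir`. [read_scenario()] reloads an equal
#' scenario.
#'
#' @param scn A `scenario`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scn, dir) {
  stopifnot(inherits(scn, "scenario"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(scn$scores, file.path(dir, "scores.csv"))
  if (!is.null(scn$hr)) readr::write_csv(scn$hr, file.path(dir, "hr.csv"))
  jsonlite::write_json(
    list(name = scn$name, n_games = scn$n_games, hr_max = scn$hr_max,
         session_length = scn$session_length),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Reload a scenario written by [write_scenario()]
#'
#' @param dir Directory holding `scores.csv`, `meta.json` and optionally
#'   `hr.csv`.
#' @return A `scenario`.
#' @export
read_scenario <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) {
    abort(sprintf("no scenario found in %s", dir),
          class = "adaptloop_scenario_error")
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  scores <- readr::read_csv(file.path(dir, "scores.csv"),
                            col_types = readr::cols(
                              game = readr::col_integer(),
                              score = readr::col_double()))
  hr_path <- file.path(dir, "hr.csv")
  hr <- NULL
  if (file.exists(hr_path)) {
    hr <- readr::read_csv(hr_path, col_types = readr::cols(
      game = readr::col_integer(), tick = readr::col_integer(),
      bpm = readr::col_double()))
  }
  structure(
    list(name = meta$name, n_games = as.integer(meta$n_games),
         scores = scores, hr = hr, hr_max = meta$hr_max,
         session_length = as.integer(meta$session_length)),
    class = "scenario"
  )
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario: %s> %d games, hr scripts: %s, hr_max %g bpm\n",
              x$name, x$n_games, if (is.null(x$hr)) "no" else "yes",
              x$hr_max))
  invisible(x)
}
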