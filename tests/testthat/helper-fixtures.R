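# Shared fixtures: a default config and scenario builders used across tests.

cfg <- adapt_config()

# Scenario with arbitrary score series (and optional per-game HR script
# function game -> bpm vector), bypassing the packaged generators.
custom_scenario <- function(scores, hr_fun = NULL, config = cfg) {
  n <- length(scores)
  hr <- NULL
  if (!is.null(hr_fun) && n > 0) {
    hr <- dplyr::bind_rows(lapply(seq_len(n), function(g) {
      tibble::tibble(game = g, tick = seq_len(config$session_length),
                     bpm = hr_fun(g))
    }))
  }
  structure(
    list(name = "custom", n_games = n,
         scores = tibble::tibble(game = seq_len(max(n, 0)), score = scores),
         hr = hr, hr_max = config$hr_max,
         session_length = config$session_length),
    class = "scenario"
  )
}

# Independent OLS oracle: slope from stats::lm over the trailing window.
ols_slope_oracle <- function(scores, window = 5) {
  y <- tail(scores, min(window, length(scores)))
  x <- seq_along(y) - 1
  unname(coef(lm(y ~ x))[2])
}
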