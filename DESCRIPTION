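Package: adaptloop
Title: Decoupled Personalization Loop for Adaptive Serious Health Games
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a decoupled dynamic-difficulty-adjustment loop for
    serious health games: a knowledge base of per-feature expert functions
    (a heart-rate ceiling and a sliding-window score-trend estimator),
    feature/action abstraction layers that keep the personalization core
    game-agnostic, a pluggable rule-model engine with offline and real-time
    modes, a simulated shoulder-rehabilitation game, deterministic study
    scenarios, and a study runner that compares offline against real-time
    adaptation and derives timing metrics from the difficulty traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
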