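scn_hr <- make_scenario("rising_hr")

test_that("offline loop on the rising-HR scenario follows the hand-traced rules", {
  res <- run_offline_loop(scn_hr, "offline_score_hr", cfg)
  trace <- res$trace$end_difficulty
  # hold at 0.8 while the sub-ceiling heart rate rises, then -0.05/game
  # once the session mean exceeds 180 (first in game 27, acting from 28)
  expect_equal(trace[1:27], rep(0.8, 27))
  expect_equal(trace[28:30], c(0.75, 0.70, 0.65))
  expect_equal(res$metrics$first_decrease_game, 28)
  expect_equal(res$metrics$argmin_game, 30)
  expect_equal(res$metrics$min_difficulty, 0.65)
  # every delta after the breach is the safety decrement
  late <- dplyr::filter(res$commands, game >= 27)
  expect_true(all(late$delta == -0.05))
})

test_that("offline loop mode and input guards hold", {
  expect_error(run_offline_loop(scn_hr, "realtime_score_hr", cfg),
               class = "adaptloop_mode_error")
  expect_error(run_realtime_loop(make_scenario("constant_score"), config = cfg),
               class = "adaptloop_mode_error")
  empty <- custom_scenario(numeric(0))
  res <- run_offline_loop(empty, "offline_score", cfg)
  expect_equal(nrow(res$trace), 0)
  expect_equal(nrow(res$commands), 0)
  expect_length(res$metrics, 0)
})

test_that("score-only offline runs reproduce the three captioned behaviors", {
  res_const <- run_offline_loop(make_scenario("constant_score"),
                                "offline_score", cfg)
  d_const <- res_const$trace$end_difficulty
  # once the window sits inside the constant tail: slow +0.01/game rise
  expect_equal(diff(d_const[18:30]), rep(0.01, 12))
  expect_true(all(diff(d_const[15:30]) > 0))

  res_up <- run_offline_loop(make_scenario("upward_score"),
                             "offline_score", cfg)
  d_up <- res_up$trace$end_difficulty
  expect_gt(mean(diff(d_up[18:30])), mean(diff(d_const[18:30])))
  expect_true(all(diff(d_up[19:30]) > 0.01))  # markedly faster than the hold rate

  res_down <- run_offline_loop(make_scenario("downward_score"),
                               "offline_score", cfg)
  deltas_down <- dplyr::filter(res_down$commands,
                               game >= 20, game <= 26)$delta
  expect_length(deltas_down, 7)
  expect_true(all(deltas_down < 0))
})

test_that("real-time loop reacts within the session that crosses the ceiling", {
  res <- run_realtime_loop(scn_hr, config = cfg)
  trace <- res$trace$end_difficulty
  expect_equal(trace[1:25], rep(0.8, 25))
  expect_lt(trace[26], 0.8)
  expect_equal(res$metrics$first_decrease_game, 26)
  # one immediate decrement per evaluation instant once smoothed HR stays over
  expect_equal(sum(res$commands$game == 27 & res$commands$timing == "immediate"),
               12)
  expect_equal(sum(res$commands$game == 25), 0)
  # in-session difficulty is non-increasing whenever decrements fire
  g26 <- dplyr::filter(res$in_session, game == 26)
  expect_true(all(diff(g26$difficulty) <= 0))
})

test_that("real-time run with a calm heart rate issues no immediate commands", {
  calm <- custom_scenario(rep(90, 8), hr_fun = function(g) rep(62, 60))
  res <- run_realtime_loop(calm, config = cfg)
  expect_equal(sum(res$commands$timing == "immediate"), 0)
  # constant score, flat HR: the slow score-driven rise applies instead
  expect_true(all(diff(res$trace$end_difficulty[2:8]) > 0))
})

test_that("offline in-session difficulty is constant; real-time dominates offline", {
  off <- run_offline_loop(scn_hr, "offline_score_hr", cfg)
  per_game_spread <- off$in_session |>
    dplyr::summarise(spread = diff(range(difficulty)), .by = game)
  expect_true(all(per_game_spread$spread == 0))

  rt <- run_realtime_loop(scn_hr, config = cfg)
  expect_true(all(rt$trace$end_difficulty <= off$trace$end_difficulty))
})

test_that("safety dominance: an over-ceiling session mean lowers the next game", {
  off <- run_offline_loop(scn_hr, "offline_score_hr", cfg)
  over <- which(off$trace$mean_hr > 180)
  for (g in over[over < 30]) {
    nxt <- off$trace$end_difficulty[g + 1]
    cur <- off$trace$end_difficulty[g]
    expect_true(nxt < cur || cur == cfg$d_min)
  }
})

test_that("score scaling leaves the score-driven difficulty trace unchanged", {
  base <- custom_scenario(c(60, 55, 58, 70, 82, 95, 110, 100, 96, 93))
  scaled <- custom_scenario(base$scores$score * 3.7)
  a <- run_offline_loop(base, "offline_score", cfg)
  b <- run_offline_loop(scaled, "offline_score", cfg)
  expect_equal(a$trace$end_difficulty, b$trace$end_difficulty)
})

test_that("metrics derive from the trace and recompute exactly", {
  m <- compute_metrics(c(0.8, 0.8, 0.75, 0.70, 0.65))
  expect_equal(m$first_decrease_game, 3)
  expect_equal(m$argmin_game, 5)
  expect_equal(m$min_difficulty, 0.65)

  flat <- compute_metrics(c(0.8, 0.8, 0.8))
  expect_true(is.na(flat$first_decrease_game))
  expect_equal(flat$argmin_game, 1)

  withref <- compute_metrics(c(0.8, 0.7, 0.6), reference_min = 0.65)
  expect_equal(withref$reach_game, 3)

  off <- run_offline_loop(scn_hr, "offline_score_hr", cfg)
  expect_identical(off$metrics,
                   compute_metrics(off$trace$end_difficulty))
  expect_error(compute_metrics(numeric(0)), class = "adaptloop_metrics_error")
})

test_that("loops are bit-reproducible and run_study adds the cross-mode metric", {
  a <- run_study(scn_hr, config = cfg)
  b <- run_study(scn_hr, config = cfg)
  expect_identical(tidy(a), tidy(b))
  expect_equal(a$realtime$metrics$reach_game, 27)
  g <- glance(a)
  expect_equal(nrow(g), 2)
  expect_identical(g$mode, c("offline", "realtime"))
})

test_that("the personalizer is blind to the game behind the samples", {
  # Route identical feature streams through the post-session chain twice:
  # once from simulator session records, once from a stub game that
  # fabricates the samples directly. The emitted deltas must be identical.
  prof <- player_profile(25, "male")
  kb <- kb_default(cfg)
  reg <- default_models(active = "offline_score_hr")

  chain <- function(sample_stream) {
    scores_seen <- numeric(0)
    prev_mean <- NULL
    deltas <- numeric(0)
    for (s in sample_stream) {
      pv <- personalize_post_session(
        s$samples,
        history = list(scores = scores_seen, profile = prof,
                       prev_mean = prev_mean),
        kb = kb, registry = reg, config = cfg)
      deltas <- c(deltas, if (is.null(pv)) NA_real_ else pv$delta)
      scores_seen <- c(scores_seen, s$score)
      prev_mean <- s$mean_hr
    }
    deltas
  }

  from_simulator <- lapply(1:10, function(g) {
    rec <- play_session_scripted(g, 0.8, scn_hr$scores$score[g],
                                 scenario_hr_script(scn_hr, g), cfg)
    list(score = rec$score, mean_hr = mean(rec$hr_trace),
         samples = list(
           transform_feature(list(feature = "score", value = rec$score,
                                  session = g)),
           transform_feature(list(feature = "heart_rate",
                                  value = mean(rec$hr_trace), session = g))))
  })
  from_stub <- lapply(1:10, function(g) {
    list(score = 90, mean_hr = 128 + 2 * g,
         samples = list(
           feature_sample("score", 90, g),
           feature_sample("heart_rate", 128 + 2 * g, g)))
  })
  expect_identical(chain(from_simulator), chain(from_stub))
})
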