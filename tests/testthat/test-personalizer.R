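kb <- kb_default(cfg)
hr_entry <- kb_lookup(kb, "heart_rate")
score_entry <- kb_lookup(kb, "score")
hr_ctx <- structure(list(age = 25, sex = "male", intensity = 1),
                    class = "context_bundle")

hr_sample <- function(value, session = 5, phase = "post_session", tick = NULL) {
  feature_sample("heart_rate", value, session, tick = tick, phase = phase)
}

test_that("heart-rate interpretation encodes exceedance and rising state", {
  pv <- interpret(hr_sample(185), hr_entry, hr_ctx, cfg)
  expect_equal(pv$need, 5 / 180)   # ~ +0.0278
  expect_true(pv$over_limit)
  expect_false(pv$rising)          # no previous session mean known
  expect_gt(pv$need, 0)            # over_limit implies positive need

  at <- interpret(hr_sample(180), hr_entry, hr_ctx, cfg)
  expect_equal(at$need, 0)
  expect_false(at$over_limit)

  ris <- interpret(hr_sample(150), hr_entry, hr_ctx, cfg, prev_mean = 148)
  expect_true(ris$rising)          # +2 bpm > 1 bpm threshold
  hold <- interpret(hr_sample(150), hr_entry, hr_ctx, cfg, prev_mean = 149.5)
  expect_false(hold$rising)        # within the threshold

  low <- interpret(hr_sample(60), hr_entry, hr_ctx, cfg)
  expect_lt(low$need, 0)
  expect_gte(low$need, -1)
})

test_that("score interpretation derives need from the windowed trend", {
  ctx <- structure(list(previous_scores = rep(90, 4)), class = "context_bundle")
  pv <- interpret(feature_sample("score", 90, 5), score_entry, ctx, cfg)
  expect_identical(pv$trend$cls, "constant")
  expect_equal(pv$need, 0)

  up_ctx <- structure(list(previous_scores = c(55, 62, 69, 76)),
                      class = "context_bundle")
  up <- interpret(feature_sample("score", 83, 5), score_entry, up_ctx, cfg)
  expect_identical(up$trend$cls, "upward")
  expect_equal(up$need, -up$trend$norm_slope)  # improving player: more challenge

  expect_error(interpret(feature_sample("score", 90, 5), score_entry,
                         hr_ctx, cfg),
               class = "adaptloop_interpretation_error")
})

test_that("model locator routes by phase and inputs, rejecting ambiguity", {
  reg <- default_models(active = c("offline_score_hr", "realtime_score_hr"))
  post_score <- interpret(
    feature_sample("score", 90, 5), score_entry,
    structure(list(previous_scores = rep(90, 4)), class = "context_bundle"),
    cfg)
  expect_identical(route_model(post_score, reg), "offline_score_hr")

  in_hr <- interpret(hr_sample(181, phase = "in_session", tick = 10),
                     hr_entry, hr_ctx, cfg)
  expect_identical(route_model(in_hr, reg), "realtime_score_hr")

  in_score <- post_score
  in_score$phase <- "in_session"
  in_score$feature_id <- "score"
  reg_no_rt_score <- default_models(active = "offline_score_hr")
  expect_error(route_model(in_score, reg_no_rt_score),
               class = "adaptloop_routing_error")

  both_active <- default_models(active = c("offline_score", "offline_score_hr"))
  expect_error(route_model(post_score, both_active),
               class = "adaptloop_configuration_error")
})

test_that("offline score model: slow rise when constant, slope-proportional otherwise", {
  constant <- eval_score_trend(rep(90, 5))
  expect_equal(model_offline_score(constant, cfg)$delta, 0.01)

  up <- eval_score_trend(c(55, 62, 69, 76, 83))
  expect_equal(up$norm_slope, 7 / 69)
  expect_equal(model_offline_score(up, cfg)$delta, 0.5 * 7 / 69)  # ~ +0.0507

  steep <- eval_score_trend(c(100, 70, 40, 25, 10))
  expect_lt(steep$norm_slope, -0.3)
  expect_equal(model_offline_score(steep, cfg)$delta, -0.08)  # clipped

  expect_null(model_offline_score(NULL, cfg))
  pv <- model_offline_score(up, cfg)
  expect_identical(pv$timing, "next_session")
})

test_that("offline score+HR model enforces precedence over_limit > rising > trend", {
  constant <- eval_score_trend(rep(90, 5))
  over <- interpret(hr_sample(182), hr_entry, hr_ctx, cfg, prev_mean = 180)
  expect_equal(model_offline_score_hr(constant, over, cfg)$delta, -0.05)

  rising <- interpret(hr_sample(150), hr_entry, hr_ctx, cfg, prev_mean = 148)
  expect_equal(model_offline_score_hr(constant, rising, cfg)$delta, 0)

  calm <- interpret(hr_sample(150), hr_entry, hr_ctx, cfg, prev_mean = 150)
  expect_equal(model_offline_score_hr(constant, calm, cfg)$delta, 0.01)

  # heart rate dominates even a strongly improving score
  up <- eval_score_trend(c(55, 62, 69, 76, 83))
  expect_equal(model_offline_score_hr(up, over, cfg)$delta, -0.05)

  # without HR the model degrades to the score model
  expect_equal(model_offline_score_hr(constant, NULL, cfg)$delta, 0.01)
})

test_that("real-time rule decrements immediately above the smoothed ceiling", {
  hit <- model_realtime_score_hr(180.2, 180, cfg)
  expect_equal(hit$delta, -0.02)
  expect_identical(hit$timing, "immediate")
  expect_null(model_realtime_score_hr(179.9, 180, cfg))
  expect_null(model_realtime_score_hr(180, 180, cfg))  # strict exceedance
})
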