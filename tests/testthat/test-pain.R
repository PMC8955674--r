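obs_normal <- function(...) {
  pain_observation(body_weight = 30, prev_body_weight = 30, body_temp = 36.5,
                   activity_event_times = seq(0, 300, by = 10), ...)
}

test_that("the 10% weight rule, temperature range and diarrhea flag score physiology", {
  o1 <- pain_observation(33.5, 30, 36.5)          # 11.7% gain
  expect_equal(score_physiological(o1), 1L)
  o2 <- pain_observation(31, 30, 36.5)            # 3.3%
  expect_equal(score_physiological(o2), 0L)
  o3 <- pain_observation(30, 30, 35.6)            # below the 35.8-37.4 range
  expect_equal(score_physiological(o3), 1L)
  expect_equal(score_physiological(o3, temp_rule = "above"), 0L)
  o4 <- pain_observation(30, 30, 36.5, diarrhea = TRUE)
  expect_equal(score_physiological(o4), 1L)
  # first observation: weight criterion skipped
  o5 <- pain_observation(30, NA, 36.5)
  expect_equal(score_physiological(o5), 0L)
})

test_that("posture and appearance categories are separate disjunctions", {
  expect_equal(score_posture(obs_normal()), 0L)
  expect_equal(score_appearance(obs_normal()), 0L)
  o <- obs_normal(pinched_face = TRUE)
  expect_equal(score_appearance(o), 1L)
  expect_equal(score_posture(o), 0L)
  o2 <- obs_normal(hunched_posture = TRUE)
  expect_equal(score_posture(o2), 1L)
  expect_equal(score_appearance(o2), 0L)
})

test_that("the 30-s inactivity rule is strict and counts boundary gaps", {
  expect_equal(score_activity(obs_normal()), 0L)                  # gaps of 10 s
  none <- pain_observation(30, 30, 36.5)                          # no events
  expect_equal(score_activity(none), 1L)
  late <- pain_observation(30, 30, 36.5,
                           activity_event_times = c(0, 31, seq(40, 300, 10)))
  expect_equal(score_activity(late), 1L)                          # 31 > 30
  edge <- pain_observation(30, 30, 36.5,
                           activity_event_times = c(0, 30, seq(40, 300, 10)))
  expect_equal(score_activity(edge), 0L)                          # 30 not > 30
})

test_that("total score spans 0 to 4 across the worked extremes", {
  worst <- pain_observation(33.5, 30, 35.0, diarrhea = TRUE,
                            hunched_posture = TRUE, rough_hair_coat = TRUE)
  expect_equal(total_pain_score(worst)$total, 4L)
  expect_equal(total_pain_score(obs_normal())$total, 0L)
  two <- obs_normal(hunched_posture = TRUE, reluctance_to_move = TRUE)
  expect_equal(total_pain_score(two)$total, 2L)
})

test_that("totals match a brute-force category disjunction over all flag combos", {
  flags <- c("diarrhea", "hunched_posture", "rough_hair_coat", "pinched_face",
             "distended_abdomen", "reluctance_to_move")
  for (mask in 0:(2^6 - 1)) {
    on <- as.logical(bitwAnd(mask, 2^(0:5)))
    args <- as.list(stats::setNames(on, flags))
    o <- do.call(obs_normal, args)
    s <- total_pain_score(o)
    brute <- as.integer(o$diarrhea) +
      as.integer(o$hunched_posture) +
      as.integer(o$rough_hair_coat || o$pinched_face ||
                   o$distended_abdomen || o$reluctance_to_move)
    expect_equal(s$total, brute)
    expect_true(s$total %in% 0:4)
  }
})

test_that("setting any additional flag never decreases the total", {
  base <- obs_normal(rough_hair_coat = TRUE)
  t0 <- total_pain_score(base)$total
  for (f in c("diarrhea", "hunched_posture", "pinched_face",
              "distended_abdomen", "reluctance_to_move")) {
    args <- stats::setNames(list(TRUE, TRUE), c("rough_hair_coat", f))
    more <- do.call(obs_normal, args)
    expect_gte(total_pain_score(more)$total, t0)
  }
})

test_that("observation validation rejects impossible values", {
  expect_error(pain_observation(-1, 30, 36.5), "weights")
  expect_error(pain_observation(30, 30, 36.5, activity_event_times = c(-5)),
               "within")
  expect_error(pain_observation(30, 30, NaN), "finite")
})
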