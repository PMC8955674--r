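test_that("peak-to-interval conversion is simple successive differencing", {
  pk <- rpeak_set(c(1L, 101L, 201L), c(0, 0.1, 0.2))
  s <- peaks_to_rri(pk)
  expect_equal(s$intervals, c(100, 100))
  expect_equal(s$beat_times, c(0.1, 0.2))
  pk2 <- rpeak_set(c(1L, 101L, 251L), c(0, 0.1, 0.25))
  expect_equal(peaks_to_rri(pk2)$intervals, c(100, 150))
  expect_error(peaks_to_rri(rpeak_set(1L, 0)), "insufficient beats")
})

test_that("the centered 3-min window of a 5-min constant series holds 1800 intervals", {
  s <- rri_series(rep(100, 3000))     # beats at 0.1 .. 300.0 s
  w <- window_rri(s, window_spec(180, "center"))
  expect_length(w$intervals, 1800L)
  expect_gte(min(w$beat_times), 60)
  expect_lt(max(w$beat_times), 240)
  # direct enumeration oracle
  expect_equal(w$beat_times, seq(60, 239.9, by = 0.1), tolerance = 1e-9)
})

test_that("a full-span start window is the identity and short records error", {
  s <- rri_series(rep(100, 1200))     # 120 s
  w <- window_rri(s, window_spec(120, "start"))
  expect_equal(w$intervals, s$intervals[-1200])   # last beat at t = 120 excluded
  expect_error(window_rri(s, window_spec(180)), "120.0 s")
})

test_that("out-of-bounds intervals are excluded and break successive pairs", {
  s <- rri_series(c(100, 100, 500, 100))
  scr <- screen_artifacts(s, min_rri = 50, max_rri = 300, max_rel_jump = 10)
  expect_equal(scr$labels, c("normal", "normal", "excluded", "normal"))
  p <- murihrv:::.valid_pairs(scr)
  expect_equal(p$first, 100)
  expect_equal(p$second, 100)
  expect_equal(rmssd(scr), 0)
})

test_that("relative-jump screening flags every other beat of an alternating series", {
  s <- rri_series(rep(c(60, 220), 10))
  scr <- screen_artifacts(s, min_rri = 10, max_rri = 1000, max_rel_jump = 0.5)
  # direct rule enumeration: 60 kept, 220 jumps 267% off the retained 60, ...
  expect_equal(scr$labels, rep(c("normal", "excluded"), 10))
})

test_that("screening an all-normal series is the identity and can be disabled", {
  set.seed(12)
  s <- rri_series(100 + rnorm(50, 0, 3))   # well within bounds, small jumps
  expect_identical(screen_artifacts(s), s)
  bad <- rri_series(c(100, 400, 100))
  expect_identical(screen_artifacts(bad, enabled = FALSE), bad)
})

test_that("bounds-only screening commutes with windowing", {
  set.seed(31)
  for (i in 1:200) {
    n <- sample(50:400, 1)
    ints <- exp(rnorm(n, log(100), 0.4))      # occasional out-of-bounds values
    s <- rri_series(ints)
    spec <- window_spec(duration = runif(1, 1, 0.5 * sum(ints) / 1000),
                        placement = sample(c("start", "center", "end"), 1))
    a <- screen_artifacts(window_rri(s, spec), max_rel_jump = Inf)
    b <- window_rri(screen_artifacts(s, max_rel_jump = Inf), spec)
    expect_identical(a, b)
  }
})

test_that("retained window mass is bounded by duration plus one interval", {
  set.seed(17)
  for (i in 1:50) {
    s <- random_rri(sample(100:500, 1))
    w <- window_rri(s, window_spec(5, "center"))
    scr <- screen_artifacts(w)
    expect_lte(sum(murihrv:::.retained(scr)), 5 * 1000 + 300)
  }
})
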