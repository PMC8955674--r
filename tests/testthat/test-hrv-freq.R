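make_tacho <- function(values, rate = 10) {
  structure(list(values = values, sampling_rate = rate, start_time = 0),
            class = "tachogram")
}

test_that("spline tachogram reproduces constants and smooth modulation", {
  s <- rri_series(rep(100, 50))
  t1 <- build_tachogram(s)
  expect_true(all(abs(t1$values - 100) < 1e-9))
  expect_equal(t1$sampling_rate, 10)

  # slow sinusoid sampled every 100 ms: spline error < 0.1 ms vs analytic curve
  bt <- seq(0.1, 60, by = 0.1)
  v <- 100 + 5 * sin(2 * pi * 0.2 * bt)
  s2 <- rri_series(v, beat_times = bt)
  t2 <- build_tachogram(s2)
  grid <- seq(bt[1], bt[length(bt)], by = 0.1)
  inner <- grid > 1 & grid < 59     # away from the natural-spline ends
  expect_lt(max(abs(t2$values[inner] - (100 + 5 * sin(2 * pi * 0.2 * grid[inner])))),
            0.1)

  expect_error(build_tachogram(rri_series(c(100, 100, 100))), ">= 4")
})

test_that("Welch integral satisfies Parseval on white noise", {
  rel_err <- vapply(1:50, function(s) {
    set.seed(s)
    x <- rnorm(2048, 0, 3)
    est <- welch_psd(make_tacho(x), welch_config(segment_length = 256))
    tot <- sum(diff(est$frequencies) *
                 (est$psd[-1] + est$psd[-length(est$psd)]) / 2)
    tot / var(x) - 1
  }, numeric(1))
  expect_lt(abs(mean(rel_err)), 0.05)
})

test_that("a pure tone lands in its bin with power a^2/2", {
  a <- 4
  x <- a * sin(2 * pi * 2 * (0:4095) / 10)
  est <- welch_psd(make_tacho(x), welch_config(segment_length = 512))
  peak <- est$frequencies[which.max(est$psd)]
  expect_lt(abs(peak - 2), 10 / 512 + 1e-9)
  expect_lt(abs(band_power(est, c(1.8, 2.2)) / (a^2 / 2) - 1), 0.1)
})

test_that("zero input gives an identically zero spectrum", {
  est <- welch_psd(make_tacho(rep(0, 1024)))
  expect_true(all(est$psd == 0))
  expect_error(welch_psd(make_tacho(rnorm(100))), "exceeds")
})

test_that("band integration is pro-rata at edges and additive", {
  est <- structure(list(frequencies = seq(0, 5, by = 0.5),
                        psd = rep(1, 11), segment_count = 1L),
                   class = "spectral_estimate")
  expect_equal(band_power(est, c(0.1, 1.0)), 0.9)
  expect_equal(band_power(est, c(1.0, 4.0)), 3.0)
  full <- band_power(est, c(0, 5))
  parts <- band_power(est, c(0, 1.3)) + band_power(est, c(1.3, 2.05)) +
    band_power(est, c(2.05, 5))
  expect_equal(parts, full, tolerance = 1e-9)
  expect_error(band_power(est, c(2, 1)), "inverted")
  expect_error(band_power(est, c(1, 9)), "Nyquist")
})

test_that("band powers are specific to the modulated band", {
  hf_only <- generate_rri(rr_synth_config(mean_rr = 100, lf_amp = 0,
                                          hf_amp = 5, hf_freq = 2,
                                          jitter_sd = 0, duration = 300))
  f1 <- freq_metrics(hf_only$series)
  expect_gt(f1$hf_power / (f1$lf_power + f1$hf_power), 0.8)

  lf_only <- generate_rri(rr_synth_config(mean_rr = 100, lf_amp = 5,
                                          lf_freq = 0.4, hf_amp = 0,
                                          jitter_sd = 0, duration = 300))
  f2 <- freq_metrics(lf_only$series)
  expect_gt(f2$lf_power / (f2$lf_power + f2$hf_power), 0.8)

  const <- rri_series(rep(100, 2000))
  f3 <- freq_metrics(const)
  expect_lt(f3$lf_power, 1e-6)
  expect_lt(f3$hf_power, 1e-6)
  expect_true(is.na(f3$lf_hf) || f3$lf_hf > 0)
})

test_that("band power scales with the square of modulation amplitude", {
  pow <- vapply(c(2, 4), function(a) {
    g <- generate_rri(rr_synth_config(mean_rr = 100, lf_amp = 0, hf_amp = a,
                                      hf_freq = 2.5, jitter_sd = 0,
                                      duration = 300))
    freq_metrics(g$series)$hf_power
  }, numeric(1))
  expect_lt(abs(pow[2] / pow[1] - 4), 0.4)
})

test_that("band powers ignore the tachogram mean level", {
  set.seed(3)
  x <- 5 * sin(2 * pi * 2 * (0:2047) / 10)
  e1 <- welch_psd(make_tacho(x))
  e2 <- welch_psd(make_tacho(x + 140))
  expect_equal(band_power(e1, c(1, 4)), band_power(e2, c(1, 4)),
               tolerance = 1e-9)
})
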