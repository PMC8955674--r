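test_that("a constant configuration yields a deterministic constant process", {
  cfg <- rr_synth_config(mean_rr = 100, lf_amp = 0, hf_amp = 0,
                         jitter_sd = 0, duration = 1)
  g <- generate_rri(cfg)
  expect_length(g$series$intervals, 10L)
  expect_equal(g$series$intervals, rep(100, 10))
  expect_equal(g$truth$beat_times, seq(0, 1, by = 0.1))
})

test_that("zero-mean sinusoidal modulation leaves the sample mean near mean_rr", {
  cfg <- rr_synth_config(mean_rr = 100, lf_amp = 0, hf_amp = 5, hf_freq = 2,
                         jitter_sd = 0, duration = 180)
  g <- generate_rri(cfg)
  expect_lt(abs(mean(g$series$intervals) - 100), 0.5)
})

test_that("identical seeds reproduce bit-identical output", {
  cfg <- rr_synth_config(jitter_sd = 3, duration = 30, seed = 99L)
  expect_identical(generate_rri(cfg), generate_rri(cfg))
  rr <- generate_rri(cfg)$series
  ec <- ecg_synth_config(noise_sd = 0.05, seed = 5L)
  expect_identical(generate_ecg(rr, ec), generate_ecg(rr, ec))
})

test_that("all generated intervals are positive over many random valid configs", {
  set.seed(41)
  for (i in 1:1000) {
    m <- runif(1, 80, 150)
    la <- runif(1, 0, m / 8)
    ha <- runif(1, 0, m / 8)
    js <- runif(1, 0, (m - la - ha) / 4 * 0.9)
    cfg <- rr_synth_config(mean_rr = m, lf_amp = la, lf_freq = runif(1, .11, .99),
                           hf_amp = ha, hf_freq = runif(1, 1.01, 3.99),
                           jitter_sd = js, duration = 3, seed = i)
    expect_true(all(generate_rri(cfg)$series$intervals > 0))
  }
})

test_that("invalid generator configurations are rejected by name", {
  expect_error(rr_synth_config(mean_rr = -5), "mean_rr")
  expect_error(rr_synth_config(lf_amp = 1, lf_freq = 1.5), "lf_freq")
  expect_error(rr_synth_config(hf_amp = 1, hf_freq = 0.5), "hf_freq")
  expect_error(rr_synth_config(jitter_sd = -1), "jitter_sd")
  expect_error(rr_synth_config(mean_rr = 100, lf_amp = 50, hf_amp = 50,
                               jitter_sd = 10), "positive intervals")
})

test_that("with no jitter the resampled series concentrates power at the set tones", {
  cfg <- rr_synth_config(mean_rr = 100, lf_amp = 4, lf_freq = 0.4,
                         hf_amp = 0, jitter_sd = 0, duration = 300)
  g <- generate_rri(cfg)
  est <- welch_psd(build_tachogram(g$series))
  nyq <- max(est$frequencies)
  in_band <- band_power(est, c(0.3, 0.5))
  non_dc <- band_power(est, c(0.05, nyq))
  expect_gt(in_band / non_dc, 0.9)

  cfg2 <- rr_synth_config(mean_rr = 100, lf_amp = 0, hf_amp = 4,
                          hf_freq = 2.5, jitter_sd = 0, duration = 300)
  est2 <- welch_psd(build_tachogram(generate_rri(cfg2)$series))
  expect_gt(band_power(est2, c(2.4, 2.6)) / band_power(est2, c(0.05, nyq)), 0.9)
})

test_that("noiseless template maxima coincide with ground-truth R times", {
  rr <- rri_series(rep(100, 30))
  e <- generate_ecg(rr, ecg_synth_config())
  fs <- e$record$sampling_rate
  for (bt in e$truth$beat_times) {
    i0 <- round(bt * fs) + 1L
    win <- max(1L, i0 - 20L):(i0 + 20L)
    expect_equal(win[which.max(e$record$samples[win])], i0)
  }
})

test_that("an empty RRI series yields a baseline-only record with zero beats", {
  e <- generate_ecg(rri_series(numeric(0)),
                    ecg_synth_config(baseline_wander_amp = 0.1))
  expect_length(e$truth$beat_times, 0L)
  expect_gt(length(e$record$samples), 0L)
  expect_lt(max(abs(e$record$samples)), 0.11)
})

test_that("a template whose R deflection is not dominant is rejected", {
  tp <- mouse_pqrst_template()
  tp$amplitude[tp$wave == "T"] <- 1.2
  expect_error(ecg_synth_config(template_params = tp), "dominant")
})

test_that("sampling rates too low for the template are rejected", {
  rr <- rri_series(rep(100, 5))
  expect_error(generate_ecg(rr, ecg_synth_config(sampling_rate = 500)),
               "samples per")
})

test_that("the analytic RMSSD formula matches simulation", {
  cfg <- rr_synth_config(mean_rr = 120, lf_amp = 4, lf_freq = 0.4,
                         hf_amp = 5, hf_freq = 2.5, jitter_sd = 3,
                         duration = 600, seed = 11L)
  g <- generate_rri(cfg)
  expect_lt(abs(rmssd(g$series) / expected_rmssd(cfg) - 1), 0.1)
  # inversion round-trip
  expect_equal(jitter_for_rmssd(expected_rmssd(cfg), cfg), cfg$jitter_sd,
               tolerance = 1e-10)
})
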