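test_that("the passband rejects DC and out-of-band tones per the analytic response", {
  fs <- 1000
  t <- (0:(10 * fs - 1)) / fs
  mid <- 2000:8000
  amp <- function(y) sqrt(2 * mean(y[mid]^2))

  dc <- bandpass(ecg_record(rep(5, 10 * fs), fs))
  expect_lt(max(abs(dc$samples)), 0.5)

  # analytic two-pass Butterworth magnitude as the oracle
  bf <- signal::butter(3, c(0.5, 50) / (fs / 2), type = "pass")
  h <- signal::freqz(bf, Fs = fs, n = 8192)
  gain2 <- function(f) abs(h$h[which.min(abs(h$f - f))])^2

  s10 <- bandpass(ecg_record(sin(2 * pi * 10 * t), fs))
  expect_equal(amp(s10$samples), gain2(10), tolerance = 0.01)
  expect_gt(amp(s10$samples), 0.95)
  expect_lt(amp(s10$samples), 1.005)

  s200 <- bandpass(ecg_record(sin(2 * pi * 200 * t), fs))
  expect_equal(amp(s200$samples), gain2(200), tolerance = 0.15)
  expect_lt(amp(s200$samples), 0.05)
})

test_that("zero-phase filtering leaves midband peaks in place and length unchanged", {
  fs <- 1000
  t <- (0:(4 * fs - 1)) / fs
  x <- sin(2 * pi * 10 * t)
  y <- bandpass(ecg_record(x, fs))
  expect_length(y$samples, length(x))
  # group-delay-free: cross-correlation of input and output peaks at lag 0
  lags <- -20:20
  cc <- vapply(lags, function(l) {
    idx <- 1001:3000
    sum(x[idx] * y$samples[idx + l])
  }, numeric(1))
  expect_lte(abs(lags[which.max(cc)]), 1L)
})

test_that("filtering is linear and never adds energy to white noise", {
  fs <- 1000
  set.seed(2)
  x <- rnorm(3 * fs)
  y <- rnorm(3 * fs)
  a <- 2.5; b <- -1.2
  fx <- bandpass(ecg_record(x, fs))$samples
  fy <- bandpass(ecg_record(y, fs))$samples
  fxy <- bandpass(ecg_record(a * x + b * y, fs))$samples
  # IIR recursions accumulate rounding error with near-unit-circle poles,
  # so linearity holds to ~1e-7 rather than machine precision
  expect_equal(fxy, a * fx + b * fy, tolerance = 1e-6)
  for (s in 1:5) {
    set.seed(s)
    w <- rnorm(3 * fs)
    expect_lte(sum(bandpass(ecg_record(w, fs))$samples^2), sum(w^2))
  }
})

test_that("band edges above Nyquist are rejected", {
  expect_error(bandpass(ecg_record(rnorm(100), 80), filter_spec(high_cut = 50)),
               "Nyquist")
  expect_error(filter_spec(low_cut = 60, high_cut = 50), "low_cut")
})

test_that("decimation preserves in-band tones and arithmetic of the factor", {
  fs <- 32000
  t <- (0:(2 * fs - 1)) / fs
  rec <- ecg_record(sin(2 * pi * 5 * t), fs)
  dec <- decimate_ecg(rec, 2000)
  expect_equal(dec$sampling_rate, 2000)
  expect_lte(abs(length(dec$samples) - length(rec$samples) / 16), 1)
  mid <- 1000:3000
  expect_lt(abs(sqrt(2 * mean(dec$samples[mid]^2)) - 1), 0.02)
})

test_that("decimation suppresses energy above the target Nyquist by >= 40 dB", {
  fs <- 32000
  t <- (0:(2 * fs - 1)) / fs
  alias <- decimate_ecg(ecg_record(sin(2 * pi * 1500 * t), fs), 2000)
  rms_out <- sqrt(mean(alias$samples[1000:3000]^2))
  expect_lt(20 * log10(rms_out / sqrt(0.5)), -40)
})

test_that("upsampling requests are rejected", {
  rec <- ecg_record(rnorm(100), 32000)
  expect_error(decimate_ecg(rec, 64000), "below the source")
})
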