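#' Configuration for the synthetic RR-interval generator
#'
#' Parameters of an integral-pulse-frequency-modulation (IPFM) style
#' generator producing mouse-scale beat times with sinusoidal low- and
#' high-frequency autonomic modulation plus white beat-to-beat jitter.
#'
#' Murine HRV analysis uses modulation bands of 0.1--1.0 Hz (LF) and
#' 1.0--4 Hz (HF); the generator's modulation frequencies must fall
#' strictly inside those bands so that generated power lands where the
#' spectral metrics expect it.
#'
#' @param mean_rr Mean R-R interval in ms (mouse scale is roughly
#'   90--150 ms).
#' @param lf_amp,hf_amp Peak amplitude of the LF / HF sinusoidal
#'   modulation, in ms. Zero disables the band.
#' @param lf_freq,hf_freq Modulation frequencies in Hz; `lf_freq` must lie
#'   in (0.1, 1.0), `hf_freq` in (1.0, 4.0).
#' @param jitter_sd Standard deviation of independent zero-mean Gaussian
#'   beat-to-beat noise, in ms. White jitter of sd `s` yields an expected
#'   RMSSD of `sqrt(2) * s`.
#' @param duration Minimum span of the generated series, in seconds.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return An object of class `rr_synth_config`.
#' @export
rr_synth_config <- function(mean_rr = 100, lf_amp = 2, lf_freq = 0.4,
                            hf_amp = 2, hf_freq = 2.5, jitter_sd = 2,
                            duration = 300, seed = 1L) {
  if (!is.numeric(mean_rr) || mean_rr <= 0)
    stop("invalid config: mean_rr must be > 0", call. = FALSE)
  if (lf_amp < 0 || hf_amp < 0)
    stop("invalid config: modulation amplitudes must be >= 0", call. = FALSE)
  if (lf_amp > 0 && (lf_freq <= 0.1 || lf_freq >= 1.0))
    stop("invalid config: lf_freq must lie in (0.1, 1.0) Hz", call. = FALSE)
  if (hf_amp > 0 && (hf_freq <= 1.0 || hf_freq >= 4.0))
    stop("invalid config: hf_freq must lie in (1.0, 4.0) Hz", call. = FALSE)
  if (jitter_sd < 0)
    stop("invalid config: jitter_sd must be >= 0", call. = FALSE)
  if (duration <= 0)
    stop("invalid config: duration must be > 0", call. = FALSE)
  if (lf_amp + hf_amp + 4 * jitter_sd >= mean_rr)
    stop("invalid config: lf_amp + hf_amp + 4*jitter_sd must be < mean_rr ",
         "(guarantees strictly positive intervals)", call. = FALSE)
  structure(list(mean_rr = mean_rr, lf_amp = lf_amp, lf_freq = lf_freq,
                 hf_amp = hf_amp, hf_freq = hf_freq, jitter_sd = jitter_sd,
                 duration = duration, seed = as.integer(seed)),
            class = "rr_synth_config")
}

#' Generate a synthetic RR-interval series with known ground truth
#'
#' Beat times follow an interval-sampling approximation of IPFM: the
#' instantaneous interval is
#' `RR(t) = mean_rr + lf_amp*sin(2*pi*lf_freq*t) + hf_amp*sin(2*pi*hf_freq*t)`
#' and the i-th interval equals `RR` evaluated at the (i-1)-th beat time
#' plus independent Gaussian jitter. Generation continues until the series
#' spans at least `duration` seconds.
#'
#' @param config An [rr_synth_config()].
#' @return A list with components `series` (an [rri_series()] whose beat
#'   times mark the beat *ending* each interval) and `truth` (class
#'   `hrv_ground_truth`: `beat_times` including the initial beat at 0,
#'   `true_rri`, and `band_fractions` — the analytic share of interval
#'   variance contributed by the LF band, HF band, and jitter).
#' @export
generate_rri <- function(config) {
  stopifnot(inherits(config, "rr_synth_config"))
  set.seed(config$seed)
  # cap guarantees positivity for |jitter| <= 4 sd; resample rare tail draws
  n_guess <- ceiling(config$duration * 1000 / config$mean_rr * 1.5) + 8L
  times <- numeric(n_guess + 1L)
  ints <- numeric(n_guess)
  t_cur <- 0
  i <- 0L
  while (t_cur < config$duration - 1e-9) {   # tolerance absorbs float drift
    i <- i + 1L
    if (i > length(ints)) {            # extend (rare: heavy jitter draws)
      ints <- c(ints, numeric(n_guess))
      times <- c(times, numeric(n_guess))
    }
    rr <- config$mean_rr +
      config$lf_amp * sin(2 * pi * config$lf_freq * t_cur) +
      config$hf_amp * sin(2 * pi * config$hf_freq * t_cur)
    if (config$jitter_sd > 0) {
      repeat {
        eps <- stats::rnorm(1L, 0, config$jitter_sd)
        if (abs(eps) <= 4 * config$jitter_sd) break
      }
      rr <- rr + eps
    }
    ints[i] <- rr
    t_cur <- t_cur + rr / 1000
    times[i + 1L] <- t_cur
  }
  ints <- ints[seq_len(i)]
  times <- times[seq_len(i + 1L)]
  var_lf <- config$lf_amp^2 / 2
  var_hf <- config$hf_amp^2 / 2
  var_j <- config$jitter_sd^2
  tot <- var_lf + var_hf + var_j
  fr <- if (tot > 0) c(lf = var_lf, hf = var_hf, jitter = var_j) / tot
        else c(lf = 0, hf = 0, jitter = 0)
  truth <- structure(list(beat_times = times, true_rri = ints,
                          band_fractions = fr),
                     class = "hrv_ground_truth")
  list(series = rri_series(ints, beat_times = times[-1L]), truth = truth)
}

#' Expected RMSSD of a synthetic RR configuration
#'
#' Closed form for the root-mean-square successive difference implied by a
#' generator configuration: sinusoidal modulation of amplitude `A` at
#' frequency `f`, sampled approximately every `T = mean_rr` seconds,
#' contributes `2 A^2 sin^2(pi f T)` to the mean squared successive
#' difference, and white jitter of sd `s` contributes `2 s^2`.
#'
#' @param config An [rr_synth_config()].
#' @return Expected RMSSD in ms.
#' @export
expected_rmssd <- function(config) {
  stopifnot(inherits(config, "rr_synth_config"))
  T_s <- config$mean_rr / 1000
  msd <- 2 * config$jitter_sd^2 +
    2 * config$lf_amp^2 * sin(pi * config$lf_freq * T_s)^2 +
    2 * config$hf_amp^2 * sin(pi * config$hf_freq * T_s)^2
  sqrt(msd)
}

#' Jitter level needed to hit a target RMSSD
#'
#' Inverts [expected_rmssd()] for the jitter term: given the sinusoidal
#' modulation in `config`, returns the white-jitter sd whose addition
#' makes the expected RMSSD equal `target_rmssd`.
#'
#' @param target_rmssd Desired RMSSD in ms.
#' @param config An [rr_synth_config()] supplying the modulation terms
#'   (its own `jitter_sd` is ignored).
#' @return Jitter sd in ms.
#' @export
jitter_for_rmssd <- function(target_rmssd, config) {
  stopifnot(inherits(config, "rr_synth_config"))
  T_s <- config$mean_rr / 1000
  mod <- 2 * config$lf_amp^2 * sin(pi * config$lf_freq * T_s)^2 +
    2 * config$hf_amp^2 * sin(pi * config$hf_freq * T_s)^2
  if (target_rmssd^2 < mod)
    stop("target RMSSD below the floor set by sinusoidal modulation",
         call. = FALSE)
  sqrt((target_rmssd^2 - mod) / 2)
}
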