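#' Default 5-Gaussian mouse PQRST template
#'
#' Each row is one Gaussian deflection: amplitude (mV), center offset from
#' the R peak (ms), and width as full-width-at-half-maximum (ms). The R
#' component dominates (1 mV, ~5 ms FWHM) so that the QRS duration matches
#' rodent physiology; P and T are placed for a ~100 ms cycle.
#'
#' @return A data.frame with columns `wave`, `amplitude`, `center`, `width`.
#' @export
mouse_pqrst_template <- function() {
  data.frame(
    wave = c("P", "Q", "R", "S", "T"),
    amplitude = c(0.15, -0.20, 1.00, -0.25, 0.30),
    center = c(-30, -7, 0, 7, 28),
    width = c(12, 5, 5, 5, 18),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic ECG waveform generator
#'
#' @param sampling_rate Sampling rate in Hz. The default 2 kHz keeps
#'   simulations light while resolving the narrowest template component
#'   with at least 10 samples per width; 32 kHz telemetry-grade output is
#'   supported by changing this value.
#' @param template_params Data frame of Gaussian components with columns
#'   `amplitude` (mV), `center` (ms offset from R), `width` (ms, FWHM);
#'   see [mouse_pqrst_template()]. The R component (offset 0) must have
#'   strictly the largest amplitude.
#' @param noise_sd Additive white Gaussian noise sd, mV.
#' @param baseline_wander_amp,baseline_wander_freq Amplitude (mV) and
#'   frequency (Hz) of a single-tone sinusoidal baseline drift;
#'   respiration-scale 0.3 Hz by default.
#' @param seed Integer seed for the noise stream.
#' @return An object of class `ecg_synth_config`.
#' @export
ecg_synth_config <- function(sampling_rate = 2000,
                             template_params = mouse_pqrst_template(),
                             noise_sd = 0, baseline_wander_amp = 0,
                             baseline_wander_freq = 0.3, seed = 1L) {
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("invalid config: sampling_rate must be > 0", call. = FALSE)
  tp <- as.data.frame(template_params)
  if (!all(c("amplitude", "center", "width") %in% names(tp)))
    stop("invalid config: template_params needs amplitude/center/width",
         call. = FALSE)
  if (any(tp$width <= 0))
    stop("invalid config: template widths must be > 0", call. = FALSE)
  r_idx <- which.max(abs(tp$amplitude))
  if (tp$center[r_idx] != 0 ||
      any(abs(tp$amplitude[-r_idx]) >= abs(tp$amplitude[r_idx])))
    stop("invalid config: the R component (center offset 0) must have ",
         "strictly dominant amplitude", call. = FALSE)
  if (noise_sd < 0 || baseline_wander_amp < 0)
    stop("invalid config: noise amplitudes must be >= 0", call. = FALSE)
  structure(list(sampling_rate = sampling_rate, template_params = tp,
                 noise_sd = noise_sd,
                 baseline_wander_amp = baseline_wander_amp,
                 baseline_wander_freq = baseline_wander_freq,
                 seed = as.integer(seed)),
            class = "ecg_synth_config")
}

#' Synthesize an ECG waveform from an RR-interval series
#'
#' Places one PQRST Gaussian-sum template per beat, centered at each beat
#' (R) time, then adds sinusoidal baseline wander and white Gaussian
#' noise. Beat times are taken as the cumulative interval sums preceded by
#' an initial beat at the start of the record (matching the convention of
#' [generate_rri()], whose ground-truth beat times this reproduces to
#' within one sample).
#'
#' @param rri An [rri_series()]; an empty series yields a baseline-only
#'   record with zero beats.
#' @param config An [ecg_synth_config()]. The sampling rate must resolve
#'   the narrowest template component with at least 10 samples per width.
#' @return A list with `record` (an [ecg_record()]) and `truth` (class
#'   `hrv_ground_truth` holding the template R-center times).
#' @export
generate_ecg <- function(rri, config = ecg_synth_config()) {
  stopifnot(inherits(rri, "rri_series"), inherits(config, "ecg_synth_config"))
  fs <- config$sampling_rate
  tp <- config$template_params
  if (fs * min(tp$width) / 1000 < 10)
    stop("sampling_rate too low: need >= 10 samples per narrowest ",
         "template width", call. = FALSE)
  sd_ms <- tp$width / (2 * sqrt(2 * log(2)))   # FWHM -> Gaussian sd
  half_span <- max(abs(tp$center) + 4 * sd_ms) / 1000
  if (length(rri$intervals) == 0L) {
    beat_times <- numeric(0)
    t_end <- 1
  } else {
    first_r <- rri$beat_times[1L] - rri$intervals[1L] / 1000
    # lead-in keeps the first template fully inside the record: a beat cut
    # off at the record edge creates a spurious filtering transient
    beat_times <- c(first_r, rri$beat_times) - first_r + half_span
    t_end <- beat_times[length(beat_times)] + half_span
  }
  n <- ceiling(t_end * fs) + 1L
  tt <- (seq_len(n) - 1L) / fs
  x <- numeric(n)
  for (bt in beat_times) {
    lo <- max(1L, floor((bt - half_span) * fs) + 1L)
    hi <- min(n, ceiling((bt + half_span) * fs) + 1L)
    tl <- tt[lo:hi]
    seg <- numeric(hi - lo + 1L)
    for (k in seq_len(nrow(tp))) {
      mu <- bt + tp$center[k] / 1000
      seg <- seg + tp$amplitude[k] * exp(-(tl - mu)^2 / (2 * (sd_ms[k] / 1000)^2))
    }
    x[lo:hi] <- x[lo:hi] + seg
  }
  if (config$baseline_wander_amp > 0)
    x <- x + config$baseline_wander_amp *
      sin(2 * pi * config$baseline_wander_freq * tt)
  if (config$noise_sd > 0) {
    set.seed(config$seed)
    x <- x + stats::rnorm(n, 0, config$noise_sd)
  }
  truth <- structure(list(beat_times = beat_times,
                          true_rri = rri$intervals,
                          band_fractions = NULL),
                     class = "hrv_ground_truth")
  list(record = ecg_record(x, sampling_rate = fs), truth = truth)
}

#' Root-mean-square amplitude of the noiseless template waveform
#'
#' Utility for scaling noise to a target signal-to-noise ratio: returns
#' the RMS of the beat template train for a given mean RR, so that
#' `noise_sd = rms / 10^(snr_db/20)` realizes `snr_db`.
#'
#' @param mean_rr Mean R-R interval, ms.
#' @param config An [ecg_synth_config()] supplying the template.
#' @return RMS amplitude in mV.
#' @export
template_rms <- function(mean_rr = 100, config = ecg_synth_config()) {
  ints <- rep(mean_rr, 20L)
  g <- generate_ecg(rri_series(ints, beat_times = cumsum(ints) / 1000),
                    ecg_synth_config(sampling_rate = config$sampling_rate,
                                     template_params = config$template_params))
  sqrt(mean(g$record$samples^2))
}
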