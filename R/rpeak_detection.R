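#' Pan-Tompkins style detector configuration, mouse scale
#'
#' The classic QRS detector chain (derivative, squaring, moving-window
#' integration, adaptive dual thresholds with search-back) with constants
#' rescaled from human to murine physiology: the integration window is
#' 12 ms (approximate rodent QRS width; the human original uses 150 ms)
#' and the refractory period 30 ms (guarding against the ~2000 bpm upper
#' bound of mouse heart rate).
#'
#' @param derivative_span Samples in the derivative stencil (fixed
#'   five-point centered stencil; values other than 5 are rejected).
#' @param integration_window Moving-window integration length, ms.
#' @param refractory Minimum separation between accepted peaks, ms.
#' @param threshold_signal_frac Position of the detection threshold
#'   between the running noise and signal levels (classic value 0.25).
#' @param threshold_noise_frac Fraction of the detection threshold used
#'   when searching back for a missed beat (classic value 0.5).
#' @param searchback_factor Gap, as a multiple of the running mean RR,
#'   that triggers search-back (> 1).
#' @param refine_window Half-width (ms) of the window around each accepted
#'   integrated-signal peak searched for the local maximum of the
#'   *filtered* ECG; integration delays peaks by roughly the integration
#'   window, and refinement restores the ms-scale timing that RR-interval
#'   metrics need.
#' @param min_signal_noise_ratio Additional acceptance guard: a candidate
#'   must exceed this multiple of the running noise level. True QRS
#'   energy exceeds the guard by orders of magnitude; it only suppresses
#'   acceptances when signal and noise levels have collapsed together.
#' @param max_rhythm_cv Record-level signal-quality gate: after
#'   detection, if the robust coefficient of variation of the detected
#'   R-R intervals (IQR / median) exceeds this value the record is
#'   declared to contain no reliable cardiac rhythm and an empty peak set
#'   is returned. Cardiac detections are quasi-periodic (robust CV well
#'   below 0.1 in mice) while detections on beat-free noise are chaotic
#'   (robust CV above 0.7); the gate is what keeps false detections on
#'   noise-only records near zero. Set `Inf` to disable.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(derivative_span = 5L, integration_window = 12,
                            refractory = 30, threshold_signal_frac = 0.25,
                            threshold_noise_frac = 0.5,
                            searchback_factor = 1.66, refine_window = 10,
                            min_signal_noise_ratio = 4,
                            max_rhythm_cv = 0.4) {
  if (derivative_span != 5L)
    stop("only the five-point derivative stencil is supported", call. = FALSE)
  if (integration_window <= 0) stop("integration_window must be > 0",
                                    call. = FALSE)
  if (refractory <= 0) stop("refractory must be > 0", call. = FALSE)
  if (threshold_signal_frac <= 0 || threshold_signal_frac >= 1 ||
      threshold_noise_frac <= 0 || threshold_noise_frac >= 1)
    stop("threshold fractions must lie in (0, 1)", call. = FALSE)
  if (searchback_factor <= 1) stop("searchback_factor must be > 1",
                                   call. = FALSE)
  structure(list(derivative_span = 5L,
                 integration_window = integration_window,
                 refractory = refractory,
                 threshold_signal_frac = threshold_signal_frac,
                 threshold_noise_frac = threshold_noise_frac,
                 searchback_factor = searchback_factor,
                 refine_window = refine_window,
                 min_signal_noise_ratio = min_signal_noise_ratio,
                 max_rhythm_cv = max_rhythm_cv),
            class = "detector_config")
}

#' Detected R-peak set
#'
#' @param indices 1-based sample positions, strictly increasing.
#' @param times Peak times in seconds.
#' @param scores Detection scores (integrated-signal peak heights), a.u.
#' @return An object of class `rpeak_set`.
#' @export
rpeak_set <- function(indices, times, scores = rep(NA_real_, length(indices))) {
  if (length(indices) > 1L && any(diff(times) <= 0))
    stop("peak times must be strictly increasing", call. = FALSE)
  structure(list(indices = as.integer(indices), times = as.numeric(times),
                 scores = as.numeric(scores)),
            class = "rpeak_set")
}

#' @export
print.rpeak_set <- function(x, ...) {
  cat(sprintf("<rpeak_set> %d peaks", length(x$times)))
  if (length(x$times) > 1L)
    cat(sprintf(", mean RR %.1f ms", mean(diff(x$times)) * 1000))
  cat("\n")
  invisible(x)
}

# one detector pass over a fixed polarity; returns accepted candidate indices
.pt_detect_one <- function(x, fs, cfg) {
  n <- length(x)
  # five-point derivative (centered), squared, moving-window integrated
  d <- numeric(n)
  d[3:(n - 2)] <- (-x[1:(n - 4)] - 2 * x[2:(n - 3)] +
                     2 * x[4:(n - 1)] + x[5:n]) / 8
  s <- d * d
  w <- max(1L, round(cfg$integration_window * fs / 1000))
  mwi <- as.numeric(stats::filter(s, rep(1 / w, w), sides = 1))
  mwi[seq_len(min(w - 1L, n))][is.na(mwi[seq_len(min(w - 1L, n))])] <- 0
  # candidate peaks: local maxima of the integrated signal (ties -> earliest)
  core <- mwi[2:(n - 1)]
  cand <- which(core > mwi[1:(n - 2)] & core >= mwi[3:n]) + 1L
  if (!length(cand)) return(list(accepted = integer(0), mwi = mwi))
  init <- mwi[seq_len(min(n, round(2 * fs)))]
  spki <- 0.7 * max(init)
  npki <- 0.5 * mean(init)
  refr <- cfg$refractory / 1000
  guard <- cfg$min_signal_noise_ratio
  acc_idx <- integer(0)
  acc_t <- numeric(0)
  rr_hist <- numeric(0)
  cand_t <- (cand - 1L) / fs
  for (j in seq_along(cand)) {
    thr1 <- npki + cfg$threshold_signal_frac * (spki - npki)
    t_j <- cand_t[j]
    p <- mwi[cand[j]]
    if (length(acc_t) >= 2L && length(rr_hist)) {
      rr_mean <- mean(utils::tail(rr_hist, 8L))
      if (t_j - acc_t[length(acc_t)] > cfg$searchback_factor * rr_mean) {
        # search-back: best skipped candidate in the gap at a lowered threshold
        gap <- which(cand_t > acc_t[length(acc_t)] + refr & cand_t < t_j)
        gap <- setdiff(gap, match(acc_idx, cand))
        if (length(gap)) {
          pg <- mwi[cand[gap]]
          best <- gap[which.max(pg)]
          thr2 <- cfg$threshold_noise_frac * thr1
          if (pg[which.max(pg)] > thr2 &&
              pg[which.max(pg)] > cfg$threshold_noise_frac * guard * npki) {
            spki <- 0.25 * mwi[cand[best]] + 0.75 * spki
            acc_idx <- c(acc_idx, cand[best])
            acc_t <- c(acc_t, cand_t[best])
            o <- order(acc_t)
            acc_idx <- acc_idx[o]; acc_t <- acc_t[o]
            rr_hist <- diff(acc_t)
            thr1 <- npki + cfg$threshold_signal_frac * (spki - npki)
          }
        }
      }
    }
    if (length(acc_t) && t_j - acc_t[length(acc_t)] < refr) next
    if (p > thr1 && p > guard * npki) {
      spki <- 0.125 * p + 0.875 * spki
      if (length(acc_t)) rr_hist <- c(rr_hist, t_j - acc_t[length(acc_t)])
      acc_idx <- c(acc_idx, cand[j])
      acc_t <- c(acc_t, t_j)
    } else {
      npki <- 0.125 * p + 0.875 * npki
    }
  }
  list(accepted = acc_idx, mwi = mwi)
}

.refine_peaks <- function(sig, idx, half) {
  n <- length(sig)
  vapply(idx, function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    lo + which.max(sig[lo:hi]) - 1L   # which.max: earliest on plateaus
  }, integer(1))
}

#' Detect R peaks in a filtered ECG record
#'
#' The derivative-squaring-integration stages are polarity-invariant, so
#' detection runs once; electrode polarity is then resolved at the
#' refinement stage by refining each accepted peak against both the
#' signal and its negation and keeping the orientation with the larger
#' mean refined peak amplitude (the R deflection dominates either way).
#' Each accepted peak is refined to the local maximum of the filtered ECG
#' within `refine_window`; plateau ties resolve to the earliest sample.
#' The refractory separation is enforced structurally after refinement.
#'
#' @param record A filtered [ecg_record()] at working rate, >= 2 s long.
#' @param config A [detector_config()].
#' @return An [rpeak_set()]. A zero-variance record yields an empty set.
#' @export
detect_rpeaks <- function(record, config = detector_config()) {
  stopifnot(inherits(record, "ecg_record"), inherits(config, "detector_config"))
  x <- record$samples
  fs <- record$sampling_rate
  if (length(x) < 2 * fs)
    stop("record shorter than the 2 s threshold-initialization span",
         call. = FALSE)
  if (stats::sd(x) == 0)
    return(rpeak_set(integer(0), numeric(0), numeric(0)))
  res <- .pt_detect_one(x, fs, config)
  if (!length(res$accepted))
    return(rpeak_set(integer(0), numeric(0), numeric(0)))
  half <- max(1L, as.integer(round(config$refine_window * fs / 1000)))
  # the causal moving-window integration delays its peak by roughly half
  # the integration window; recenter before searching the filtered ECG
  lag <- as.integer(max(1L, round(config$integration_window * fs / 1000)) %/% 2L)
  centers <- pmax(1L, res$accepted - lag)
  ref_pos <- .refine_peaks(x, centers, half)
  ref_neg <- .refine_peaks(-x, centers, half)
  if (mean(-x[ref_neg]) > mean(x[ref_pos])) {
    refined <- ref_neg; sig <- -x
  } else {
    refined <- ref_pos; sig <- x
  }
  scores <- res$mwi[res$accepted]
  o <- order(refined)
  refined <- refined[o]; scores <- scores[o]
  # structural refractory enforcement after refinement
  keep <- !duplicated(refined)
  refined <- refined[keep]; scores <- scores[keep]
  refr_samp <- config$refractory / 1000 * fs
  out_i <- integer(0); out_s <- numeric(0)
  for (k in seq_along(refined)) {
    if (length(out_i) && refined[k] - out_i[length(out_i)] < refr_samp) {
      if (scores[k] > out_s[length(out_s)]) {  # keep the stronger of the pair
        out_i[length(out_i)] <- refined[k]
        out_s[length(out_s)] <- scores[k]
      }
    } else {
      out_i <- c(out_i, refined[k])
      out_s <- c(out_s, scores[k])
    }
  }
  # rhythm-plausibility gate: chaotic inter-detection intervals mean the
  # record holds no usable cardiac rhythm (e.g. a beat-free noise record)
  if (length(out_i) >= 4L) {
    rr <- diff(out_i) / fs
    if (stats::IQR(rr) / stats::median(rr) > config$max_rhythm_cv)
      return(rpeak_set(integer(0), numeric(0), numeric(0)))
  }
  rpeak_set(out_i, (out_i - 1L) / fs, out_s)
}

#' Match detected peaks to ground truth
#'
#' Greedy one-to-one nearest matching within a tolerance: candidate pairs
#' are ranked by absolute timing error and matched smallest-error first,
#' each detection and each true beat used at most once.
#'
#' @param detected An [rpeak_set()].
#' @param truth A ground-truth object with `beat_times` (e.g. from
#'   [generate_rri()] / [generate_ecg()]), or a numeric vector of times.
#' @param tol Matching tolerance, ms.
#' @return A list: `sensitivity` (matched / true beats), `ppv`
#'   (matched / detections), `timing_errors` (signed, ms, one per match),
#'   `n_matched`.
#' @export
match_to_truth <- function(detected, truth, tol = 5) {
  stopifnot(inherits(detected, "rpeak_set"))
  tt <- if (is.numeric(truth)) truth else truth$beat_times
  dt <- detected$times
  if (!length(tt) && !length(dt))
    return(list(sensitivity = 1, ppv = 1, timing_errors = numeric(0),
                n_matched = 0L))
  if (!length(tt) || !length(dt))
    return(list(sensitivity = if (length(tt)) 0 else 1,
                ppv = if (length(dt)) 0 else 1,
                timing_errors = numeric(0), n_matched = 0L))
  tol_s <- tol / 1000
  # candidate pairs within tolerance, via a window over the sorted truth
  lo <- findInterval(dt - tol_s, tt) + 1L
  hi <- findInterval(dt + tol_s, tt)
  di <- rep.int(seq_along(dt), pmax(0L, hi - lo + 1L))
  ti <- unlist(lapply(seq_along(dt), function(i)
    if (hi[i] >= lo[i]) lo[i]:hi[i] else integer(0)))
  if (!length(di))
    return(list(sensitivity = 0, ppv = 0, timing_errors = numeric(0),
                n_matched = 0L))
  err <- dt[di] - tt[ti]
  o <- order(abs(err))
  used_d <- logical(length(dt)); used_t <- logical(length(tt))
  keep <- logical(length(o))
  for (k in o) {
    if (!used_d[di[k]] && !used_t[ti[k]]) {
      used_d[di[k]] <- TRUE; used_t[ti[k]] <- TRUE; keep[k] <- TRUE
    }
  }
  m <- sum(keep)
  list(sensitivity = m / length(tt), ppv = m / length(dt),
       timing_errors = err[keep] * 1000, n_matched = m)
}
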