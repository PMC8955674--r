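#' Convert detected R peaks to an R-R interval series
#'
#' The i-th interval is the time between successive R peaks i and i+1 in
#' ms; each interval is stamped with the time of the beat *ending* it.
#'
#' @param peaks An [rpeak_set()] with at least two peaks.
#' @return An [rri_series()] of `length(peaks) - 1` intervals.
#' @export
peaks_to_rri <- function(peaks) {
  stopifnot(inherits(peaks, "rpeak_set"))
  if (length(peaks$times) < 2L)
    stop("insufficient beats: need >= 2 R peaks to form an interval",
         call. = FALSE)
  rri_series(diff(peaks$times) * 1000, beat_times = peaks$times[-1L])
}

#' Analysis window specification
#'
#' Murine short-term HRV is computed on a 3-minute window of a 5-minute
#' recording; `placement` chooses which 3 minutes. The default, `center`,
#' avoids handling-stress transients at the recording edges.
#'
#' @param duration Window length, s (> 0).
#' @param placement One of `"start"`, `"center"`, `"end"`.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(duration = 180, placement = c("center", "start", "end")) {
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  structure(list(duration = duration, placement = match.arg(placement)),
            class = "window_spec")
}

.series_span <- function(series) {
  if (!length(series$intervals)) return(c(0, 0))
  c(series$beat_times[1L] - series$intervals[1L] / 1000,
    series$beat_times[length(series$beat_times)])
}

#' Restrict an RRI series to an analysis window
#'
#' Keeps exactly those intervals whose *ending* beat time falls in the
#' half-open window `[t0, t0 + duration)`, with `t0` set by the placement
#' rule relative to the series span (start of first interval to last
#' beat).
#'
#' @param series An [rri_series()] spanning at least `spec$duration`.
#' @param spec A [window_spec()].
#' @return The windowed [rri_series()].
#' @export
window_rri <- function(series, spec = window_spec()) {
  stopifnot(inherits(series, "rri_series"), inherits(spec, "window_spec"))
  span <- .series_span(series)
  avail <- span[2L] - span[1L]
  if (avail < spec$duration)
    stop(sprintf("recording spans %.1f s, shorter than the %.1f s window",
                 avail, spec$duration), call. = FALSE)
  t0 <- switch(spec$placement,
               start = span[1L],
               center = span[1L] + (avail - spec$duration) / 2,
               end = span[2L] - spec$duration)
  keep <- series$beat_times >= t0 & series$beat_times < t0 + spec$duration
  rri_series(series$intervals[keep], beat_times = series$beat_times[keep],
             labels = series$labels[keep])
}

#' Flag physiologically implausible intervals
#'
#' An interval is flagged `excluded` when it falls outside
#' `[min_rri, max_rri]` or differs from the previous *retained* interval
#' by more than `max_rel_jump` (relative). Excluded intervals contribute
#' to no HRV metric, and successive-difference metrics only use pairs of
#' adjacent retained intervals with no exclusion between them. The study
#' species reports no artifact handling, so defaults are permissive;
#' pass `enabled = FALSE` to disable screening entirely.
#'
#' @param series An [rri_series()].
#' @param min_rri,max_rri Plausible interval bounds, ms.
#' @param max_rel_jump Maximum relative beat-to-beat change (fraction).
#' @param enabled Set `FALSE` to return the series unchanged.
#' @return The series with updated quality labels.
#' @export
screen_artifacts <- function(series, min_rri = 50, max_rri = 300,
                             max_rel_jump = 0.3, enabled = TRUE) {
  stopifnot(inherits(series, "rri_series"))
  if (!enabled || !length(series$intervals)) return(series)
  if (min_rri <= 0 || min_rri >= max_rri)
    stop("need 0 < min_rri < max_rri", call. = FALSE)
  labels <- series$labels
  prev <- NA_real_
  for (i in seq_along(series$intervals)) {
    if (labels[i] == "excluded") next
    v <- series$intervals[i]
    bad <- v < min_rri || v > max_rri ||
      (!is.na(prev) && abs(v - prev) / prev > max_rel_jump)
    if (bad) labels[i] <- "excluded" else prev <- v
  }
  rri_series(series$intervals, beat_times = series$beat_times, labels = labels)
}

# retained intervals and the valid adjacent pairs for successive-difference
# metrics (both members retained, adjacent in the original series)
.retained <- function(series) series$intervals[series$labels == "normal"]

.valid_pairs <- function(series) {
  ok <- series$labels == "normal"
  i <- which(ok[-length(ok)] & ok[-1L])
  list(first = series$intervals[i], second = series$intervals[i + 1L])
}
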