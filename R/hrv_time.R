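#' Mean R-R interval
#'
#' Arithmetic mean of the retained intervals, ms. Longer mean RRI means a
#' slower heart rate; in mice the healthy resting scale is roughly
#' 100--150 ms.
#'
#' @param series An [rri_series()] with at least one retained interval.
#' @return Mean RRI, ms.
#' @export
mean_rri <- function(series) {
  stopifnot(inherits(series, "rri_series"))
  x <- .retained(series)
  if (!length(x)) stop("no retained intervals", call. = FALSE)
  mean(x)
}

#' Root mean square of successive differences (RMSSD)
#'
#' `sqrt(mean((RR[i+1] - RR[i])^2))` over valid adjacent retained pairs —
#' the denominator is the number of pairs used (N - 1 for an unscreened
#' series of N intervals). RMSSD indexes parasympathetic (vagal)
#' activity.
#'
#' @param series An [rri_series()] with at least one valid adjacent pair.
#' @return RMSSD, ms.
#' @export
rmssd <- function(series) {
  stopifnot(inherits(series, "rri_series"))
  p <- .valid_pairs(series)
  if (!length(p$first))
    stop("no valid adjacent interval pair", call. = FALSE)
  sqrt(mean((p$second - p$first)^2))
}

#' Percentage of successive differences exceeding 5 ms (pNN5)
#'
#' The rodent analogue of human pNN50: the percentage of valid adjacent
#' retained pairs whose successive difference exceeds 5 ms (strict
#' inequality). The threshold is compared against the absolute difference
#' by default; `absolute = FALSE` counts only positive (lengthening)
#' differences.
#'
#' @param series An [rri_series()] with at least one valid adjacent pair.
#' @param threshold Difference threshold, ms.
#' @param absolute Compare `|diff|` (default) or signed `diff`.
#' @return pNN5 in percent (0--100).
#' @export
pnn5 <- function(series, threshold = 5, absolute = TRUE) {
  stopifnot(inherits(series, "rri_series"))
  p <- .valid_pairs(series)
  if (!length(p$first))
    stop("no valid adjacent interval pair", call. = FALSE)
  d <- p$second - p$first
  if (absolute) d <- abs(d)
  100 * sum(d > threshold) / length(d)
}

#' All time-domain HRV metrics for one window
#'
#' @param series A windowed, screened [rri_series()].
#' @return A list of class `hrv_time` with `mean_rri`, `rmssd`, `pnn5`
#'   (ms, ms, %), `n_intervals` (retained count) and `n_pairs` (valid
#'   adjacent pairs).
#' @export
hrv_time_metrics <- function(series) {
  stopifnot(inherits(series, "rri_series"))
  structure(list(mean_rri = mean_rri(series), rmssd = rmssd(series),
                 pnn5 = pnn5(series),
                 n_intervals = length(.retained(series)),
                 n_pairs = length(.valid_pairs(series)$first)),
            class = "hrv_time")
}
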