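#' Single-channel ECG record
#'
#' @param samples Numeric vector of voltage samples, mV; all finite.
#' @param sampling_rate Sampling rate in Hz, > 0.
#' @param subject_id,timepoint,channel Optional labels.
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(samples, sampling_rate, subject_id = NA_character_,
                       timepoint = NA_character_, channel = "ECG") {
  samples <- as.numeric(samples)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      is.na(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be a single positive number", call. = FALSE)
  if (length(samples) && any(!is.finite(samples)))
    stop("all samples must be finite", call. = FALSE)
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 subject_id = as.character(subject_id),
                 timepoint = as.character(timepoint),
                 channel = as.character(channel)),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %d samples @ %g Hz (%.2f s)",
              length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate))
  if (!is.na(x$subject_id)) cat(" subject:", x$subject_id)
  if (!is.na(x$timepoint)) cat(" timepoint:", x$timepoint)
  cat("\n")
  invisible(x)
}

#' R-R interval series
#'
#' Ordered R-R intervals in ms with the absolute time (s) of the beat
#' *ending* each interval, plus a per-interval quality label used by
#' artifact screening.
#'
#' @param intervals Numeric vector of intervals, ms; all > 0.
#' @param beat_times Strictly increasing times (s) of the ending beats;
#'   defaults to the cumulative interval sum.
#' @param labels Character vector in `{"normal","excluded"}`.
#' @return An object of class `rri_series`.
#' @export
rri_series <- function(intervals,
                       beat_times = cumsum(intervals) / 1000,
                       labels = rep("normal", length(intervals))) {
  intervals <- as.numeric(intervals)
  beat_times <- as.numeric(beat_times)
  if (length(intervals) && any(intervals <= 0))
    stop("all intervals must be > 0", call. = FALSE)
  if (length(beat_times) != length(intervals))
    stop("beat_times and intervals must have equal length", call. = FALSE)
  if (length(beat_times) > 1L && any(diff(beat_times) <= 0))
    stop("beat_times must be strictly increasing", call. = FALSE)
  if (!all(labels %in% c("normal", "excluded")))
    stop("labels must be 'normal' or 'excluded'", call. = FALSE)
  structure(list(intervals = intervals, beat_times = beat_times,
                 labels = as.character(labels)),
            class = "rri_series")
}

#' @export
print.rri_series <- function(x, ...) {
  n <- length(x$intervals)
  cat(sprintf("<rri_series> %d intervals (%d excluded)", n,
              sum(x$labels == "excluded")))
  if (n) cat(sprintf(", span %.1f s, mean %.1f ms",
                     diff(range(c(x$beat_times[1L] - x$intervals[1L] / 1000,
                                  x$beat_times))),
                     mean(x$intervals[x$labels == "normal"])))
  cat("\n")
  invisible(x)
}

# native text format: '#' comments, 'key=value' header lines, then data lines
.read_keyed_lines <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  is_hdr <- grepl("=", lines, fixed = TRUE)
  kv <- strsplit(lines[is_hdr], "=", fixed = TRUE)
  header <- stats::setNames(
    vapply(kv, function(p) trimws(paste(p[-1L], collapse = "=")), ""),
    vapply(kv, function(p) trimws(p[1L]), ""))
  list(header = header, data = lines[!is_hdr], lineno = lineno[!is_hdr])
}

.header_rate <- function(header, path) {
  if (!"sampling_rate_hz" %in% names(header))
    stop("format error in '", path, "': header lacks sampling_rate_hz",
         call. = FALSE)
  fs <- suppressWarnings(as.numeric(header[["sampling_rate_hz"]]))
  if (is.na(fs) || fs <= 0)
    stop("format error in '", path, "': sampling_rate_hz must be a ",
         "positive number", call. = FALSE)
  fs
}

#' Read an ECG record from the native delimited-text format
#'
#' The format is UTF-8 text: `#`-prefixed comment lines, `key=value`
#' header lines (at minimum `sampling_rate_hz`; optionally `subject_id`,
#' `timepoint`, `channel`), then one voltage sample (mV) per line.
#'
#' @param path File path.
#' @return An [ecg_record()].
#' @export
read_ecg <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  p <- .read_keyed_lines(path)
  fs <- .header_rate(p$header, path)
  vals <- suppressWarnings(as.numeric(p$data))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L]
    stop("format error in '", path, "' line ", p$lineno[bad],
         ": non-numeric sample '", p$data[bad], "'", call. = FALSE)
  }
  hget <- function(k, d) if (k %in% names(p$header)) p$header[[k]] else d
  ecg_record(vals, sampling_rate = fs,
             subject_id = hget("subject_id", NA_character_),
             timepoint = hget("timepoint", NA_character_),
             channel = hget("channel", "ECG"))
}

#' Write an ECG record to the native text format
#'
#' Values are written with 9 significant digits, so
#' `read_ecg(write_ecg(x))` round-trips to that precision.
#'
#' @param record An [ecg_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ecg <- function(record, path) {
  stopifnot(inherits(record, "ecg_record"))
  hdr <- c("# murihrv ECG record",
           sprintf("sampling_rate_hz=%.9g", record$sampling_rate))
  if (!is.na(record$subject_id))
    hdr <- c(hdr, paste0("subject_id=", record$subject_id))
  if (!is.na(record$timepoint))
    hdr <- c(hdr, paste0("timepoint=", record$timepoint))
  hdr <- c(hdr, paste0("channel=", record$channel))
  writeLines(c(hdr, sprintf("%.9g", record$samples)), path, useBytes = TRUE)
  invisible(path)
}

#' Read an RR-interval series from the native text format
#'
#' Data lines hold `interval_ms time_s` (whitespace-separated); an
#' optional third column carries the quality label.
#'
#' @param path File path.
#' @return An [rri_series()].
#' @export
read_rri <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  p <- .read_keyed_lines(path)
  if (!length(p$data)) return(rri_series(numeric(0), numeric(0)))
  parts <- strsplit(trimws(p$data), "\\s+")
  ints <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
  tms <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  if (anyNA(ints) || anyNA(tms)) {
    bad <- which(is.na(ints) | is.na(tms))[1L]
    stop("format error in '", path, "' line ", p$lineno[bad],
         ": expected 'interval_ms time_s'", call. = FALSE)
  }
  if (any(ints <= 0)) {
    bad <- which(ints <= 0)[1L]
    stop("validation error in '", path, "' line ", p$lineno[bad],
         ": non-positive interval ", ints[bad], " ms", call. = FALSE)
  }
  labels <- vapply(parts, function(x)
    if (length(x) >= 3L) x[3L] else "normal", "")
  rri_series(ints, beat_times = tms, labels = labels)
}

#' Write an RR-interval series to the native text format
#'
#' @param series An [rri_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rri <- function(series, path) {
  stopifnot(inherits(series, "rri_series"))
  lines <- c("# murihrv RRI series: interval_ms time_s label",
             sprintf("%.9g %.9g %s", series$intervals, series$beat_times,
                     series$labels))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Allowed study group labels
#' @export
study_groups <- function() c("naive", "cancer", "cancer_saline",
                             "cancer_tramadol")

#' Write a long-format study results table as CSV
#'
#' Enforces the fixed column order `subject_id, group, timepoint, metric,
#' value`, validates group labels against [study_groups()], and checks
#' that each (subject, timepoint, metric) combination is unique.
#'
#' @param table Data frame with the five columns above.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  cols <- c("subject_id", "group", "timepoint", "metric", "value")
  if (!all(cols %in% names(table)))
    stop("results table must have columns: ", paste(cols, collapse = ", "),
         call. = FALSE)
  if (!all(table$group %in% study_groups()))
    stop("unknown group label(s): ",
         paste(unique(setdiff(table$group, study_groups())), collapse = ", "),
         call. = FALSE)
  key <- paste(table$subject_id, table$timepoint, table$metric)
  if (anyDuplicated(key))
    stop("duplicate (subject, timepoint, metric) rows", call. = FALSE)
  utils::write.csv(table[cols], path, row.names = FALSE)
  invisible(path)
}
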