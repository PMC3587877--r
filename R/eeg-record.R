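#' Construct a single-channel EEG record
#'
#' The basic signal container: an amplitude series in microvolts, its
#' sampling rate, and a table of labelled, non-overlapping anesthesia-state
#' segments (half-open intervals `[start_s, end_s)` in seconds from record
#' start).
#'
#' @param samples Numeric vector of amplitudes (microvolts).
#' @param fs_hz Sampling rate in Hz (positive).
#' @param segments Data frame with columns `start_s`, `end_s`, `label`.
#' @param channel Montage string, e.g. `"FPZ"`.
#'
#' @return An object of class `eeg_record`.
#' @export
eeg_record <- function(samples, fs_hz, segments, channel = "FPZ") {
  if (fs_hz <= 0) abort("fs_hz must be positive.")
  segments <- as_tibble(segments)
  stopifnot(all(c("start_s", "end_s", "label") %in% names(segments)))
  assert_state(segments$label, "segment label")
  duration <- length(samples) / fs_hz
  segments <- dplyr::arrange(segments, .data$start_s)
  if (any(segments$end_s <= segments$start_s)) {
    abort("Each segment must satisfy end_s > start_s.")
  }
  if (any(segments$end_s > duration + 1e-9)) {
    abort(sprintf(
      "Segment labels exceed the record duration (%.2f s).", duration
    ))
  }
  if (nrow(segments) > 1 &&
      any(segments$start_s[-1] < segments$end_s[-nrow(segments)] - 1e-9)) {
    abort("Segments must be non-overlapping.")
  }
  structure(
    list(
      samples = as.numeric(samples),
      fs_hz = fs_hz,
      segments = segments,
      channel = channel
    ),
    class = "eeg_record"
  )
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf(
    "<eeg_record> %d samples @ %g Hz (%.1f s), channel %s, %d segment(s)\n",
    length(x$samples), x$fs_hz, length(x$samples) / x$fs_hz,
    x$channel, nrow(x$segments)
  ))
  print(x$segments)
  invisible(x)
}

#' Record duration in seconds
#' @param rec An [eeg_record()].
#' @return Duration in seconds.
#' @export
record_duration <- function(rec) {
  length(rec$samples) / rec$fs_hz
}

#' Coerce an EEG record to a tibble
#'
#' @param x An [eeg_record()].
#' @param ... Unused.
#' @return Tibble with columns `time_s`, `amplitude_uV`, `label` (the state
#'   label of the segment each sample falls in, `NA` outside all segments).
#' @export
as_tibble.eeg_record <- function(x, ...) {
  t <- (seq_along(x$samples) - 1) / x$fs_hz
  lab <- rep(NA_character_, length(t))
  for (i in seq_len(nrow(x$segments))) {
    inside <- t >= x$segments$start_s[i] & t < x$segments$end_s[i]
    lab[inside] <- x$segments$label[i]
  }
  tibble(time_s = t, amplitude_uV = x$samples, label = lab)
}
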