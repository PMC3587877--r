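# Time-domain burst-suppression detection and the BS% characteristic.

#' Detect suppression episodes in an epoch
#'
#' A sample is flagged as suppressed iff it lies inside a contiguous run
#' where `|x| <= threshold_uV` lasting at least `min_ms` milliseconds — the
#' standard operationalization of EEG suppression used for the burst
#' suppression ratio.
#'
#' @param x Numeric signal vector (microvolts).
#' @param fs_hz Sampling rate in Hz.
#' @param threshold_uV Amplitude criterion in microvolts (default 5).
#' @param min_ms Minimum episode duration in milliseconds (default 500).
#'
#' @return An object of class `suppression_mask`: logical per-sample flags
#'   with the parameters attached.
#' @export
#' @examples
#' m <- detect_suppression(rep(0, 256), 128)
#' bsr(m)
detect_suppression <- function(x, fs_hz, threshold_uV = 5, min_ms = 500) {
  if (threshold_uV <= 0) abort("threshold_uV must be positive.")
  quiet <- abs(x) <= threshold_uV
  min_n <- max(1L, ceiling(min_ms / 1000 * fs_hz))
  flags <- logical(length(x))
  r <- rle(quiet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (r$values[i] && r$lengths[i] >= min_n) {
      flags[starts[i]:ends[i]] <- TRUE
    }
  }
  structure(
    flags,
    threshold_uV = threshold_uV,
    min_ms = min_ms,
    fs_hz = fs_hz,
    class = "suppression_mask"
  )
}

#' Burst suppression ratio (BS%)
#'
#' Percentage of samples flagged as suppressed: `100 * flagged / total`.
#'
#' @param mask A [detect_suppression()] result.
#' @return Percentage in `[0, 100]`.
#' @export
bsr <- function(mask) {
  if (length(mask) == 0) abort("Empty suppression mask.")
  100 * mean(unclass(mask))
}
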