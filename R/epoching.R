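# Cutting labelled records into fixed-length analysis epochs.

#' Cut a labelled record into fixed-length epochs
#'
#' Slides a window of `epoch_s` seconds with fractional `overlap` across
#' each labelled segment. Windows lie entirely inside one segment
#' (boundary-straddling windows are dropped) and inherit the segment's
#' label. With the defaults (2 s, 50% overlap) a 60 s segment yields 59
#' epochs.
#'
#' @param rec An [eeg_record()].
#' @param epoch_s Epoch length in seconds; `epoch_s * fs_hz` must be a
#'   whole number of samples.
#' @param overlap Fractional overlap between consecutive epochs, in `[0, 1)`.
#'
#' @return A tibble with one row per epoch: `epoch` (index), `label`,
#'   `start_s` (offset in the parent record), `fs_hz`, and a `samples`
#'   list-column of numeric vectors.
#' @export
#' @examples
#' rec <- simulate_study(sim_config(duration_s_per_class = 10))
#' ep <- epochize(rec)
#' dplyr::count(ep, label)
epochize <- function(rec, epoch_s = 2, overlap = 0.5) {
  stopifnot(inherits(rec, "eeg_record"))
  if (overlap < 0 || overlap >= 1) abort("overlap must lie in [0, 1).")
  n_ep <- epoch_s * rec$fs_hz
  if (abs(n_ep - round(n_ep)) > 1e-9) {
    abort("epoch_s * fs_hz must be an integral number of samples.")
  }
  n_ep <- as.integer(round(n_ep))
  seg_durs <- rec$segments$end_s - rec$segments$start_s
  if (nrow(rec$segments) > 0 && epoch_s > min(seg_durs) + 1e-9) {
    abort(sprintf(
      "Epoch length %.3g s exceeds the shortest segment (%.3g s).",
      epoch_s, min(seg_durs)
    ))
  }
  step <- max(1L, as.integer(round(n_ep * (1 - overlap))))
  out <- list()
  for (i in seq_len(nrow(rec$segments))) {
    s0 <- as.integer(round(rec$segments$start_s[i] * rec$fs_hz)) + 1L
    s1 <- as.integer(round(rec$segments$end_s[i] * rec$fs_hz))
    starts <- seq(s0, s1 - n_ep + 1L, by = step)
    out[[i]] <- tibble(
      label = rec$segments$label[i],
      start_s = (starts - 1L) / rec$fs_hz,
      fs_hz = rec$fs_hz,
      samples = lapply(starts, function(s) rec$samples[s:(s + n_ep - 1L)])
    )
  }
  res <- dplyr::bind_rows(out)
  dplyr::mutate(res, epoch = dplyr::row_number(), .before = 1)
}

#' Remove high-amplitude artifact epochs
#'
#' Drops every epoch containing any sample whose absolute amplitude exceeds
#' `amp_limit_uV` — a guardrail against gross (e.g. movement) artifacts.
#' The number of removed epochs is reported.
#'
#' @param epochs An [epochize()] tibble.
#' @param amp_limit_uV Rejection threshold in microvolts (default 500);
#'   `Inf` keeps everything.
#' @return The filtered epoch tibble.
#' @export
reject_artifacts <- function(epochs, amp_limit_uV = 500) {
  if (amp_limit_uV <= 0) abort("amp_limit_uV must be positive.")
  bad <- purrr::map_lgl(epochs$samples, function(x) any(abs(x) > amp_limit_uV))
  if (any(bad)) {
    inform(sprintf("reject_artifacts: removed %d of %d epochs exceeding %.4g uV.",
                   sum(bad), length(bad), amp_limit_uV))
  }
  epochs[!bad, , drop = FALSE]
}
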