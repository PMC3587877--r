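# Reading and writing EEG signals (EDF 16-bit and plain CSV) and
# segment-label sidecar files.

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a single-channel EEG record as EDF
#'
#' Minimal EDF (16-bit European Data Format) writer: one signal, physical
#' dimension microvolts, a single data record holding the whole signal.
#' Amplitudes are scaled symmetrically to the 16-bit digital range, so the
#' round trip is exact to about `max(abs(x)) / 32767` microvolts.
#'
#' @param rec An [eeg_record()].
#' @param path Output file path (`.edf`).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  x <- rec$samples
  n <- length(x)
  pm <- max(abs(x), 1e-6)
  dig <- as.integer(round(x / pm * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field("X", 80),
    pad_field("eegdepth synthetic/export", 80),
    pad_field("01.01.00", 8),
    pad_field("00.00.00", 8),
    pad_field(256 * 2, 8),
    pad_field("", 44),
    pad_field(1, 8),                                 # 1 data record
    pad_field(format(n / rec$fs_hz, nsmall = 0), 8), # record duration (s)
    pad_field(1, 4)                                  # 1 signal
  )
  sig <- paste0(
    pad_field(rec$channel, 16),
    pad_field("", 80),
    pad_field("uV", 8),
    pad_field(format(-pm, digits = 6), 8),
    pad_field(format(pm, digits = 6), 8),
    pad_field(-32767, 8),
    pad_field(32767, 8),
    pad_field("", 80),
    pad_field(n, 8),
    pad_field("", 32)
  )
  writeChar(paste0(hdr, sig), con, eos = NULL)
  writeBin(dig, con, size = 2, endian = "little")
  invisible(path)
}

read_edf_header_field <- function(con, width) {
  trimws(readChar(con, width))
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readChar(con, 8)                       # version
  readChar(con, 80 + 80 + 8 + 8)         # ids, date, time
  readChar(con, 8)                       # header bytes
  readChar(con, 44)                      # reserved
  n_rec <- as.integer(read_edf_header_field(con, 8))
  rec_dur <- as.numeric(read_edf_header_field(con, 8))
  ns <- as.integer(read_edf_header_field(con, 4))
  lab <- vapply(seq_len(ns), function(i) read_edf_header_field(con, 16), "")
  readChar(con, ns * 80)                 # transducer
  readChar(con, ns * 8)                  # physical dimension
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) read_edf_header_field(con, 8), ""))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) read_edf_header_field(con, 8), ""))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) read_edf_header_field(con, 8), ""))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) read_edf_header_field(con, 8), ""))
  readChar(con, ns * 80)                 # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) read_edf_header_field(con, 8), ""))
  readChar(con, ns * 32)                 # reserved
  if (ns > 1) {
    warn(sprintf("EDF file has %d channels; using the first (%s).", ns, lab[1]))
  }
  out <- numeric(0)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[s], size = 2, endian = "little")
      if (s == 1) {
        gain <- (phys_max[1] - phys_min[1]) / (dig_max[1] - dig_min[1])
        out <- c(out, phys_min[1] + (d - dig_min[1]) * gain)
      }
    }
  }
  list(samples = out, fs_hz = spr[1] / rec_dur, channel = lab[1])
}

#' Write segment labels as CSV
#'
#' Sidecar label file with columns `start_s`, `end_s`, `label`.
#'
#' @param rec An [eeg_record()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(rec, path) {
  write.csv(rec$segments, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an EEG record (signal + labels)
#'
#' Dispatches on the signal file extension: `.edf` for EDF, `.csv` for a
#' plain `time_s,amplitude_uV` table.
#'
#' @param rec An [eeg_record()].
#' @param path Signal file path (`.edf` or `.csv`).
#' @param label_path Optional label CSV path (`start_s,end_s,label`).
#' @return `path`, invisibly.
#' @export
write_record <- function(rec, path, label_path = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "edf") {
    write_edf(rec, path)
  } else if (ext == "csv") {
    df <- data.frame(
      time_s = (seq_along(rec$samples) - 1) / rec$fs_hz,
      amplitude_uV = rec$samples
    )
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    abort(sprintf("Unknown signal file extension '%s' (use .edf or .csv).", ext))
  }
  if (!is.null(label_path)) write_labels(rec, label_path)
  invisible(path)
}

#' Read an EEG record (signal + labels)
#'
#' Reads a single-channel EEG signal from EDF or CSV (header
#' `time_s,amplitude_uV`; sampling rate inferred from the time column) and
#' a CSV label file with `start_s,end_s,label` rows, validated against the
#' record duration and the four anesthesia states. A multi-channel EDF
#' falls back to its first channel with a warning.
#'
#' @param path Signal file (`.edf` or `.csv`).
#' @param label_path Label CSV file; `NULL` labels the whole record `NA`-free
#'   with no segments.
#' @return An [eeg_record()].
#' @export
read_record <- function(path, label_path = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "edf") {
    raw <- read_edf(path)
    samples <- raw$samples
    fs <- raw$fs_hz
    channel <- raw$channel
  } else if (ext == "csv") {
    df <- read.csv(path)
    stopifnot(all(c("time_s", "amplitude_uV") %in% names(df)))
    samples <- df$amplitude_uV
    dt <- median(diff(df$time_s))
    fs <- 1 / dt
    channel <- "FPZ"
  } else {
    abort(sprintf("Unknown signal file extension '%s' (use .edf or .csv).", ext))
  }
  if (!is.finite(fs) || fs <= 0) abort("Non-positive sampling rate.")
  duration <- length(samples) / fs
  if (!is.null(label_path)) {
    seg <- read.csv(label_path, stringsAsFactors = FALSE)
    stopifnot(all(c("start_s", "end_s", "label") %in% names(seg)))
    assert_state(seg$label, "label file class")
    if (any(seg$end_s > duration + 1 / fs)) {
      abort("Label file segments exceed the signal duration.")
    }
    seg$end_s <- pmin(seg$end_s, duration)
  } else {
    seg <- tibble(start_s = numeric(0), end_s = numeric(0), label = character(0))
  }
  eeg_record(samples, fs, seg, channel = channel)
}
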