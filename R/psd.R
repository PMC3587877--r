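# Frequency-domain characteristics: Welch PSD and the features derived
# from it (SEF, MF, band powers and ratios, BIS-style beta ratio).

#' Classical EEG band edges
#'
#' Conventional qEEG band definitions used for band powers, ratios and the
#' simulator's spectral shaping: delta 0.5-4, theta 4-8, alpha 8-12,
#' beta 12-30 Hz. The analysis range is 0.5-47 Hz throughout.
#'
#' @return Named list of `c(lo_hz, hi_hz)` pairs.
#' @export
eeg_band_edges <- function() {
  list(
    delta = c(0.5, 4),
    theta = c(4, 8),
    alpha = c(8, 12),
    beta  = c(12, 30)
  )
}

analysis_range <- function() c(0.5, 47)

#' Spectral analysis configuration
#'
#' @param segment_s Welch segment length in seconds (Hann windowed).
#' @param overlap Fractional overlap between segments, in `[0, 1)`.
#' @return An object of class `spectral_config`.
#' @export
spectral_config <- function(segment_s = 1, overlap = 0.5) {
  if (overlap < 0 || overlap >= 1) abort("overlap must lie in [0, 1).")
  if (segment_s <= 0) abort("segment_s must be positive.")
  structure(list(segment_s = segment_s, overlap = overlap),
            class = "spectral_config")
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodogram: the signal is cut into Hann-windowed
#' segments of `cfg$segment_s` seconds with fractional overlap
#' `cfg$overlap`, each segment's one-sided periodogram is computed by FFT,
#' and the periodograms are averaged. Scaling is chosen so that the
#' integral of the PSD over frequency equals the signal variance
#' (Parseval consistency).
#'
#' @param x Numeric signal vector (microvolts) or a one-row epoch; see
#'   [extract_features()] for the epoch pathway.
#' @param fs_hz Sampling rate in Hz.
#' @param cfg A [spectral_config()].
#'
#' @return An object of class `psd_estimate`: a list with `freqs_hz`,
#'   `power` (uV^2/Hz), `df_hz` (grid spacing), `total_power` (uV^2
#'   integrated over the 0.5-47 Hz analysis range), and `fs_hz`.
#' @export
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 2, by = 1 / 128))
#' p <- welch_psd(x, 128)
#' p$freqs_hz[which.max(p$power)]
welch_psd <- function(x, fs_hz, cfg = spectral_config()) {
  nseg <- round(cfg$segment_s * fs_hz)
  if (length(x) < nseg) {
    abort("Signal shorter than one Welch segment.")
  }
  step <- max(1L, round(nseg * (1 - cfg$overlap)))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))  # Hann
  u <- sum(win^2)
  acc <- numeric(nseg)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- seg - mean(seg)
    X <- fft(seg * win)
    acc <- acc + Mod(X)^2
  }
  pxx <- acc / (length(starts) * u * fs_hz)
  # fold to one-sided
  half <- floor(nseg / 2) + 1L
  p1 <- pxx[seq_len(half)]
  if (nseg %% 2 == 0) {
    p1[2:(half - 1L)] <- 2 * p1[2:(half - 1L)]
  } else {
    p1[2:half] <- 2 * p1[2:half]
  }
  freqs <- (seq_len(half) - 1L) * fs_hz / nseg
  df <- fs_hz / nseg
  rng <- analysis_range()
  in_rng <- freqs >= rng[1] & freqs <= rng[2]
  structure(
    list(
      freqs_hz = freqs,
      power = p1,
      df_hz = df,
      total_power = sum(p1[in_rng]) * df,
      fs_hz = fs_hz
    ),
    class = "psd_estimate"
  )
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf(
    "<psd_estimate> %d bins, df %.3g Hz, total power (0.5-47 Hz) %.4g uV^2\n",
    length(x$freqs_hz), x$df_hz, x$total_power
  ))
  invisible(x)
}

#' Coerce a PSD estimate to a tibble
#' @param x A `psd_estimate`.
#' @param ... Unused.
#' @return Tibble with `freq_hz` and `power_uV2_hz`.
#' @export
as_tibble.psd_estimate <- function(x, ...) {
  tibble(freq_hz = x$freqs_hz, power_uV2_hz = x$power)
}

# Cumulative-power quantile frequency over the analysis range; tie-break:
# first grid frequency whose cumulative power reaches the threshold.
psd_quantile_freq <- function(psd, quantile) {
  rng <- analysis_range()
  keep <- psd$freqs_hz >= rng[1] & psd$freqs_hz <= rng[2]
  f <- psd$freqs_hz[keep]
  p <- psd$power[keep]
  tot <- sum(p)
  if (!is.finite(tot) || tot <= 0) return(feature_sentinel())
  cs <- cumsum(p) / tot
  f[which(cs >= quantile - 1e-12)[1]]
}

#' Spectral edge frequency
#'
#' The smallest frequency below which `quantile` of the spectral power in
#' the 0.5-47 Hz analysis range resides (SEF95 by default).
#'
#' @param psd A [welch_psd()] result.
#' @param quantile Power quantile, default 0.95.
#' @return Frequency in Hz, or `NA` for a zero-power spectrum.
#' @export
spectral_edge_frequency <- function(psd, quantile = 0.95) {
  psd_quantile_freq(psd, quantile)
}

#' Median power frequency
#'
#' The frequency splitting the 0.5-47 Hz spectral power in half
#' (spectral edge at quantile 0.5).
#'
#' @param psd A [welch_psd()] result.
#' @return Frequency in Hz, or `NA` for a zero-power spectrum.
#' @export
median_frequency <- function(psd) {
  psd_quantile_freq(psd, 0.5)
}

#' Absolute and relative band powers
#'
#' Integrates the PSD over each classical band and divides by the total
#' power in the 0.5-47 Hz analysis range to obtain relative ratios.
#'
#' @param psd A [welch_psd()] result.
#' @param bands Named list of band edges as in [eeg_band_edges()].
#' @return Tibble with columns `band`, `power_uV2` (absolute) and `ratio`
#'   (relative, `NA` if total power is zero).
#' @export
band_powers <- function(psd, bands = eeg_band_edges()) {
  tot <- psd$total_power
  rows <- purrr::imap(bands, function(edges, nm) {
    keep <- psd$freqs_hz >= edges[1] & psd$freqs_hz < edges[2]
    p <- sum(psd$power[keep]) * psd$df_hz
    tibble(
      band = nm,
      power_uV2 = p,
      ratio = if (tot > 0) p / tot else feature_sentinel()
    )
  })
  dplyr::bind_rows(rows)
}

#' BIS-style relative beta ratio
#'
#' The log-ratio `log10(P[30-47 Hz] / P[11-20 Hz])` of spectral power in a
#' fast band over a mid band — the "Beta Ratio" component of the BIS
#' index family, kept distinct from the plain relative beta band power.
#'
#' @param psd A [welch_psd()] result.
#' @return Dimensionless log-ratio; `NA` when either band has zero power.
#' @export
beta_ratio_bis <- function(psd) {
  num_keep <- psd$freqs_hz >= 30 & psd$freqs_hz <= 47
  den_keep <- psd$freqs_hz >= 11 & psd$freqs_hz <= 20
  num <- sum(psd$power[num_keep])
  den <- sum(psd$power[den_keep])
  if (num <= 0 || den <= 0) return(feature_sentinel())
  log10(num / den)
}
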