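# Bispectrum estimation (direct FFT method) and the SynchFastSlow ratio.

#' Direct (FFT-based) bispectrum estimate
#'
#' Cuts the signal into Hann-windowed, mean-removed segments, computes each
#' segment's FFT `X`, and averages the triple product
#' `X(f1) * X(f2) * Conj(X(f1 + f2))` across segments. The estimate is
#' returned on the principal bifrequency domain `f1 >= f2 >= 0`,
#' `f1 + f2 <= 47 Hz` (the analysis ceiling). For Gaussian noise the
#' bispectrum converges to zero with segment averaging; quadratic phase
#' coupling between `f1`, `f2` and `f1 + f2` produces a peak at `(f1, f2)`.
#'
#' @param x Numeric signal vector (microvolts).
#' @param fs_hz Sampling rate in Hz.
#' @param cfg A [spectral_config()] giving segment length and overlap.
#' @param min_segments Minimum number of averaging segments (default 8).
#'
#' @return An object of class `bispectrum_estimate`: tibble-backed grid with
#'   `f1_hz`, `f2_hz`, `magnitude`, plus attributes `n_segments` and `df_hz`.
#' @export
bispectrum <- function(x, fs_hz, cfg = spectral_config(), min_segments = 8) {
  nseg <- round(cfg$segment_s * fs_hz)
  step <- max(1L, round(nseg * (1 - cfg$overlap)))
  if (length(x) < nseg) abort("Signal shorter than one segment.")
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  if (length(starts) < min_segments) {
    abort(sprintf(
      "Bispectrum needs >= %d segments for averaging; got %d. Use shorter segments or more overlap.",
      min_segments, length(starts)
    ))
  }
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  df <- fs_hz / nseg
  i_max <- floor(47 / df)                     # analysis ceiling on f1 + f2
  half <- floor(nseg / 2)
  i_max <- min(i_max, half)
  grid <- expand.grid(i2 = 0:i_max, i1 = 0:i_max)
  grid <- grid[grid$i1 >= grid$i2 & (grid$i1 + grid$i2) <= i_max, , drop = FALSE]

  acc <- complex(length.out = nrow(grid))
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- seg - mean(seg)
    X <- fft(seg * win)
    acc <- acc + X[grid$i1 + 1L] * X[grid$i2 + 1L] * Conj(X[grid$i1 + grid$i2 + 1L])
  }
  b <- acc / length(starts)
  out <- tibble(
    f1_hz = grid$i1 * df,
    f2_hz = grid$i2 * df,
    magnitude = Mod(b)
  )
  structure(out,
    n_segments = length(starts),
    df_hz = df,
    class = c("bispectrum_estimate", class(out))
  )
}

#' SynchFastSlow bispectral ratio
#'
#' The log-ratio of summed bispectral magnitude over a broad region to that
#' over a fast region, with regions defined on the sum frequency
#' `f1 + f2`: numerator 0.5-47 Hz, denominator 40-47 Hz. This is the
#' relative fast/slow-wave synchrony characteristic derived from the
#' bispectrum in the BIS index family. Because the numerator region
#' contains the denominator region, the value is non-negative.
#'
#' @param bs A [bispectrum()] estimate.
#' @return Dimensionless log10 ratio; `NA` when the denominator region
#'   carries no bispectral magnitude.
#' @export
synch_fast_slow <- function(bs) {
  fsum <- bs$f1_hz + bs$f2_hz
  num <- sum(bs$magnitude[fsum >= 0.5 & fsum <= 47])
  den <- sum(bs$magnitude[fsum >= 40 & fsum <= 47])
  if (den <= 0) return(feature_sentinel())
  log10(num / den)
}
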