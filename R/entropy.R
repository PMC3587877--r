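# Entropy and complexity characteristics: Shannon, spectral, Renyi, SVD,
# approximate entropy, Lempel-Ziv complexity, wavelet-energy entropy.

#' Entropy/complexity configuration
#'
#' Parameters for the histogram, embedding and binarization choices behind
#' the entropy-family characteristics. Defaults follow common qEEG practice:
#' 64 amplitude bins, ApEn with embedding dimension 2 and tolerance 0.2 SD,
#' SVD embedding dimension 10 with unit delay, median binarization for
#' Lempel-Ziv, and a 4-level db4 wavelet decomposition.
#'
#' @param hist_bins Amplitude histogram bin count (>= 8).
#' @param apen_m ApEn embedding dimension (>= 1).
#' @param apen_r_frac ApEn tolerance as a fraction of the epoch SD, in (0,1).
#' @param svd_dim,svd_delay Delay-embedding dimension and lag (samples).
#' @param lz_threshold Binarization rule for Lempel-Ziv: `"median"` or `"mean"`.
#' @param wavelet_levels Wavelet decomposition depth.
#' @param renyi_eps Guard applied to tiny bin probabilities before raising
#'   them to a negative power (Renyi order -1 is numerically explosive on
#'   rare bins).
#'
#' @return An object of class `entropy_config`.
#' @export
entropy_config <- function(hist_bins = 64,
                           apen_m = 2,
                           apen_r_frac = 0.2,
                           svd_dim = 10,
                           svd_delay = 1,
                           lz_threshold = c("median", "mean"),
                           wavelet_levels = 4,
                           renyi_eps = 1e-12) {
  lz_threshold <- match.arg(lz_threshold)
  if (hist_bins < 8) abort("hist_bins must be >= 8.")
  if (apen_m < 1) abort("apen_m must be >= 1.")
  if (apen_r_frac <= 0 || apen_r_frac >= 1) abort("apen_r_frac must lie in (0, 1).")
  if (renyi_eps <= 0) abort("renyi_eps must be positive.")
  structure(
    list(
      hist_bins = hist_bins, apen_m = apen_m, apen_r_frac = apen_r_frac,
      svd_dim = svd_dim, svd_delay = svd_delay, lz_threshold = lz_threshold,
      wavelet_levels = wavelet_levels, renyi_eps = renyi_eps
    ),
    class = "entropy_config"
  )
}

# Equal-width amplitude histogram probabilities over the epoch's own range.
amplitude_probs <- function(x, bins) {
  rng <- range(x)
  if (diff(rng) == 0) return(NULL)  # constant signal
  brk <- seq(rng[1], rng[2], length.out = bins + 1)
  cnt <- tabulate(
    findInterval(x, brk, rightmost.closed = TRUE, all.inside = TRUE),
    nbins = bins
  )
  cnt / length(x)
}

#' Shannon entropy of the amplitude distribution
#'
#' `-sum(p * log2(p))` over the probabilities of an equal-width amplitude
#' histogram spanning the epoch's own range. A constant signal has entropy
#' 0 by convention; the upper bound is `log2(hist_bins)`.
#'
#' @param x Numeric signal vector.
#' @param cfg An [entropy_config()].
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(x, cfg = entropy_config()) {
  p <- amplitude_probs(x, cfg$hist_bins)
  if (is.null(p)) return(0)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Normalized spectral entropy
#'
#' Shannon entropy of the PSD normalized over the 0.5-47 Hz analysis
#' range, divided by the log of the bin count, so a pure tone scores near
#' 0 and white noise near 1.
#'
#' @param psd A [welch_psd()] result.
#' @return Value in `[0, 1]`, or `NA` for a zero-power spectrum.
#' @export
spectral_entropy <- function(psd) {
  rng <- analysis_range()
  keep <- psd$freqs_hz >= rng[1] & psd$freqs_hz <= rng[2]
  p <- psd$power[keep]
  tot <- sum(p)
  if (!is.finite(tot) || tot <= 0) return(feature_sentinel())
  q <- p / tot
  q <- q[q > 0]
  -sum(q * log(q)) / log(sum(keep))
}

#' Renyi entropy of the amplitude distribution
#'
#' `(1 / (1 - order)) * log2(sum(p^order))` over occupied histogram bins.
#' On a uniform distribution over k bins this collapses to `log2(k)` for
#' every order; the order -1 member weights rare bins heavily, so
#' zero-count bins are excluded and probabilities are floored at
#' `cfg$renyi_eps` before exponentiation.
#'
#' @param x Numeric signal vector.
#' @param order Renyi order, any real except 1 (Shannon is the limit).
#' @param cfg An [entropy_config()].
#' @return Entropy in bits; 0 when fewer than two bins are occupied.
#' @export
renyi_entropy <- function(x, order, cfg = entropy_config()) {
  if (order == 1) abort("order must differ from 1 (use shannon_entropy).")
  p <- amplitude_probs(x, cfg$hist_bins)
  if (is.null(p)) return(0)
  p <- p[p > 0]
  if (length(p) < 2) return(0)
  p <- pmax(p, cfg$renyi_eps)
  (1 / (1 - order)) * log2(sum(p^order))
}

#' Singular value decomposition entropy
#'
#' Normalized Shannon entropy of the singular-value spectrum of the
#' delay-embedding matrix: low for low-dimensional (near-periodic) signals,
#' near 1 for broadband noise.
#'
#' @param x Numeric signal vector; length must be at least
#'   `svd_dim * svd_delay`.
#' @param cfg An [entropy_config()].
#' @return Value in `[0, 1]`; 0 for a degenerate (zero) embedding matrix.
#' @export
svd_entropy <- function(x, cfg = entropy_config()) {
  d <- cfg$svd_dim
  tau <- cfg$svd_delay
  n_rows <- length(x) - (d - 1) * tau
  if (n_rows < d) abort("Signal too short for the delay embedding.")
  emb <- sapply(0:(d - 1), function(k) x[(1 + k * tau):(n_rows + k * tau)])
  s <- svd(emb, nu = 0, nv = 0)$d
  tot <- sum(s)
  if (tot <= 0) return(0)
  sb <- s / tot
  sb <- sb[sb > 0]
  -sum(sb * log(sb)) / log(d)
}

#' Approximate entropy (ApEn)
#'
#' Pincus' regularity statistic `ApEn(m, r) = Phi_m(r) - Phi_{m+1}(r)`,
#' where `Phi_m` is the mean log fraction of template matches of length
#' `m` within Chebyshev tolerance `r` (self-matches included). The
#' tolerance is `apen_r_frac` times the epoch SD. Regular signals score
#' low; irregular signals score high.
#'
#' @param x Numeric signal vector, length >= 50.
#' @param cfg An [entropy_config()].
#' @return Non-negative dimensionless value (natural-log units); 0 for a
#'   zero-variance signal.
#' @export
approximate_entropy <- function(x, cfg = entropy_config()) {
  n <- length(x)
  if (n < 50) abort("approximate_entropy needs at least 50 samples.")
  s <- sd(x)
  if (s == 0) return(0)
  r <- cfg$apen_r_frac * s
  m <- cfg$apen_m
  phi <- function(m) {
    nv <- n - m + 1
    d <- abs(outer(x[1:nv], x[1:nv], "-"))
    if (m > 1) {
      for (k in 1:(m - 1)) {
        d <- pmax(d, abs(outer(x[(1 + k):(nv + k)], x[(1 + k):(nv + k)], "-")))
      }
    }
    cnt <- rowSums(d <= r)
    mean(log(cnt / nv))
  }
  phi(m) - phi(m + 1)
}

# LZ76 exhaustive-history phrase count (Kaspar-Schuster scheme).
lz76_count <- function(s) {
  n <- length(s)
  i <- 0L; cn <- 1L; l <- 1L; k <- 1L; k_max <- 1L
  repeat {
    if (s[i + k] == s[l + k]) {
      k <- k + 1L
      if (l + k > n) { cn <- cn + 1L; break }
    } else {
      if (k > k_max) k_max <- k
      i <- i + 1L
      if (i == l) {
        cn <- cn + 1L
        l <- l + k_max
        if (l + 1L > n) break
        i <- 0L; k <- 1L; k_max <- 1L
      } else {
        k <- 1L
      }
    }
  }
  cn
}

#' Normalized Lempel-Ziv complexity
#'
#' Binarizes the signal about its median (or mean), counts the distinct
#' phrases `c(n)` of the LZ76 exhaustive parse, and normalizes by the
#' random-sequence asymptote: `C = c(n) * log2(n) / n`. Periodic signals
#' approach 0, random ones approach 1.
#'
#' @param x Numeric signal vector, length >= 32.
#' @param cfg An [entropy_config()].
#' @return Normalized complexity (dimensionless).
#' @export
lempel_ziv_complexity <- function(x, cfg = entropy_config()) {
  n <- length(x)
  if (n < 32) abort("lempel_ziv_complexity needs at least 32 samples.")
  thr <- if (cfg$lz_threshold == "median") median(x) else mean(x)
  s <- as.integer(x > thr)
  lz76_count(s) * log2(n) / n
}

# --- db4 wavelet decomposition (periodized) ----------------------------------

db4_lowpass <- function() {
  c(0.23037781330885523, 0.7148465705525415, 0.6308807679295904,
    -0.02798376941698385, -0.18703481171888114, 0.030841381835986965,
    0.032883011666982945, -0.010597401784997278)
}

# One periodized analysis step: returns approximation and detail halves.
dwt_step <- function(x, h) {
  g <- rev(h) * (-1)^(seq_along(h) - 1)
  n <- length(x)
  half <- n %/% 2
  idx <- outer(2 * seq_len(half) - 1, seq_along(h) - 1, "+")
  idx <- ((idx - 1) %% n) + 1
  xm <- matrix(x[idx], nrow = half)
  list(a = drop(xm %*% h), d = drop(xm %*% g))
}

#' Wavelet-energy entropy characteristic (WBC)
#'
#' Decomposes the epoch with a periodized db4 discrete wavelet transform to
#' `wavelet_levels` levels and returns the Shannon entropy (bits) of the
#' relative energy distribution across the detail subbands and the final
#' approximation. Energy concentrated in one subband (a band-limited tone)
#' gives a value near 0; broadband noise spreads energy and pushes the
#' value toward `log2(wavelet_levels + 1)`.
#'
#' @param x Numeric signal vector; length at least `2^wavelet_levels` (it
#'   is truncated to a multiple of `2^wavelet_levels`).
#' @param cfg An [entropy_config()].
#' @return Entropy in bits; 0 for a zero-energy signal.
#' @export
wavelet_characteristic <- function(x, cfg = entropy_config()) {
  lv <- cfg$wavelet_levels
  block <- 2^lv
  if (length(x) < block) abort("Signal shorter than 2^wavelet_levels samples.")
  n_use <- (length(x) %/% block) * block
  x <- x[seq_len(n_use)]
  h <- db4_lowpass()
  energies <- numeric(lv + 1)
  a <- x
  for (j in seq_len(lv)) {
    st <- dwt_step(a, h)
    energies[j] <- sum(st$d^2)
    a <- st$a
  }
  energies[lv + 1] <- sum(a^2)
  tot <- sum(energies)
  if (tot <= 0) return(0)
  p <- energies / tot
  p <- p[p > 0]
  -sum(p * log2(p))
}
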