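# Direct bispectrum estimator and the SynchFastSlow ratio.

fs <- 128

test_that("zero signal yields an all-zero bispectral surface", {
  bs <- bispectrum(rep(0, fs * 8), fs)
  expect_true(all(bs$magnitude == 0))
})

test_that("Gaussian noise bispectrum shrinks with segment averaging", {
  set.seed(1)
  x <- rnorm(fs * 64)
  b8 <- bispectrum(x[1:(fs * 8)], fs, spectral_config(segment_s = 1, overlap = 0))
  b64 <- bispectrum(x, fs, spectral_config(segment_s = 1, overlap = 0))
  expect_equal(attr(b8, "n_segments"), 8)
  expect_equal(attr(b64, "n_segments"), 64)
  expect_lt(median(b64$magnitude), median(b8$magnitude))
})

test_that("quadratic phase coupling produces a peak at the coupled bifrequency", {
  t <- seq(0, 16 - 1 / fs, by = 1 / fs)
  set.seed(2)
  x <- cos(2 * pi * 10 * t + 0.3) + cos(2 * pi * 15 * t + 1.1) +
    cos(2 * pi * 25 * t + 0.3 + 1.1) + 0.01 * rnorm(length(t))
  bs <- bispectrum(x, fs, spectral_config(segment_s = 1, overlap = 0.5))
  top <- bs[which.max(bs$magnitude), ]
  expect_equal(top$f1_hz, 15)
  expect_equal(top$f2_hz, 10)
})

test_that("principal-domain estimator agrees with a brute-force full FFT oracle", {
  set.seed(3)
  nseg <- 32
  x <- rnorm(fs * 4)
  cfg <- spectral_config(segment_s = nseg / fs, overlap = 0)
  bs <- bispectrum(x, fs, cfg)
  # oracle: accumulate the raw triple product over the same Hann segments
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  starts <- seq(1, length(x) - nseg + 1, by = nseg)
  df <- fs / nseg
  i_max <- min(floor(47 / df), nseg %/% 2)
  acc <- matrix(0 + 0i, i_max + 1, i_max + 1)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)]
    X <- fft((seg - mean(seg)) * win)
    for (i1 in 0:i_max) for (i2 in 0:i_max) {
      if (i1 + i2 <= i_max) {
        acc[i1 + 1, i2 + 1] <- acc[i1 + 1, i2 + 1] +
          X[i1 + 1] * X[i2 + 1] * Conj(X[i1 + i2 + 1])
      }
    }
  }
  acc <- acc / length(starts)
  # symmetry of the full-plane oracle across the f1 = f2 diagonal
  for (i1 in 0:i_max) for (i2 in 0:i1) {
    if (i1 + i2 <= i_max) {
      expect_equal(acc[i1 + 1, i2 + 1], acc[i2 + 1, i1 + 1], tolerance = 1e-10)
    }
  }
  # package values equal the oracle on the principal domain
  for (r in seq_len(nrow(bs))) {
    i1 <- round(bs$f1_hz[r] / df)
    i2 <- round(bs$f2_hz[r] / df)
    expect_equal(bs$magnitude[r], Mod(acc[i1 + 1, i2 + 1]), tolerance = 1e-8)
  }
})

test_that("SynchFastSlow responds to the slow/fast energy balance", {
  mk <- function(f1, f2, mag) {
    structure(tibble::tibble(f1_hz = f1, f2_hz = f2, magnitude = mag),
              class = c("bispectrum_estimate", "tbl_df", "tbl", "data.frame"))
  }
  # all energy inside the fast region: numerator = denominator -> 0
  expect_equal(synch_fast_slow(mk(c(40, 22), c(2, 20), c(1, 1))), 0)
  # slow energy dominates a tiny fast remainder -> large positive
  expect_gt(synch_fast_slow(mk(c(5, 41), c(5, 2), c(1000, 1))), 2)
  # adding slow-band energy never decreases the value
  base <- mk(c(10, 41), c(5, 2), c(10, 5))
  more <- mk(c(10, 41, 12), c(5, 2, 8), c(10, 5, 7))
  expect_gte(synch_fast_slow(more), synch_fast_slow(base))
  # zero denominator -> sentinel
  expect_true(is.na(synch_fast_slow(mk(10, 5, 1))))
})

test_that("too few averaging segments are rejected", {
  expect_error(bispectrum(rnorm(fs * 2), fs, spectral_config(segment_s = 1, overlap = 0)),
               "segments")
})

test_that("per-epoch SynchFastSlow is finite and deterministic", {
  feats <- default_study_features()
  expect_true(all(is.finite(feats$BSFSR)))
  ep <- epochize(simulate_study(sim_config(duration_s_per_class = 5)))
  f1 <- extract_features(ep)
  f2 <- extract_features(ep)
  expect_identical(f1$BSFSR, f2$BSFSR)
})
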