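# Entropy and complexity characteristics against closed forms and
# independent oracles.

fs <- 128

test_that("Shannon entropy: constant, uniform and bounded cases", {
  cfg <- entropy_config()
  expect_equal(shannon_entropy(rep(3, 256), cfg), 0)

  set.seed(1)
  u <- runif(2e5)
  expect_lt(abs(shannon_entropy(u, cfg) - log2(cfg$hist_bins)), 0.05)

  for (i in 1:10) {
    h <- shannon_entropy(rnorm(256), cfg)
    expect_gte(h, 0)
    expect_lte(h, log2(cfg$hist_bins))
  }
})

test_that("spectral entropy is ~0 for tones, ~1 for white noise, always in [0,1]", {
  x10 <- sin(2 * pi * 10 * seq(0, 4, by = 1 / fs))
  # a Hann-windowed tone occupies at most the ~4-bin mainlobe of the 47-bin
  # analysis range, bounding its normalized entropy by log(4)/log(47)
  expect_lt(spectral_entropy(welch_psd(x10, fs)), log(4) / log(47))

  set.seed(2)
  expect_gt(spectral_entropy(welch_psd(rnorm(fs * 60), fs)), 0.9)

  for (i in 1:10) {
    se <- spectral_entropy(welch_psd(rnorm(256) + i * x10[1:256], fs))
    expect_gte(se, 0)
    expect_lte(se, 1)
  }
  expect_true(is.na(spectral_entropy(welch_psd(rep(0, 256), fs))))
})

test_that("Renyi entropy matches closed forms and the Shannon limit", {
  cfg <- entropy_config()
  # two equal-mass levels: 1 bit at order 3 (closed form)
  x2 <- rep(c(0, 1), 128)
  expect_equal(renyi_entropy(x2, 3, cfg), 1)
  expect_equal(renyi_entropy(x2, -1, cfg), 1)

  # k equiprobable levels collapse to log2(k) for any order
  for (k in c(4, 8, 16)) {
    xk <- rep(seq(0, k - 1), each = 32)
    for (ord in c(-1, 0.5, 3)) {
      expect_equal(renyi_entropy(xk, ord, cfg), log2(k), tolerance = 1e-9)
    }
  }

  # order -> 1 approaches Shannon on the same histogram
  set.seed(3)
  x <- rnorm(1024)
  sh <- shannon_entropy(x, cfg)
  expect_lt(abs(renyi_entropy(x, 0.99, cfg) - sh), 0.02)
  expect_lt(abs(renyi_entropy(x, 1.01, cfg) - sh), 0.02)

  expect_equal(renyi_entropy(rep(1, 100), 3, cfg), 0)
  expect_error(renyi_entropy(x, 1, cfg), "order")
})

test_that("SVD entropy ranks periodic below stochastic signals and stays in [0,1]", {
  cfg <- entropy_config()
  set.seed(4)
  s_sin <- svd_entropy(sin(2 * pi * 10 * seq(0, 2, by = 1 / fs)), cfg)
  s_wn <- svd_entropy(rnorm(256), cfg)
  expect_lt(s_sin, s_wn)
  expect_gte(s_sin, 0)
  expect_lte(s_wn, 1)
  expect_equal(svd_entropy(rep(0, 256), cfg), 0)
})

test_that("approximate entropy matches the brute-force oracle to 1e-10", {
  cfg <- entropy_config()
  set.seed(5)
  for (i in 1:5) {
    x <- rnorm(200)
    expect_equal(approximate_entropy(x, cfg), apen_oracle(x), tolerance = 1e-10)
  }
})

test_that("approximate entropy: degenerate and ordering cases", {
  cfg <- entropy_config()
  expect_equal(approximate_entropy(rep(1, 100), cfg), 0)
  set.seed(6)
  t2 <- seq(0, 2, by = 1 / fs)
  expect_lt(approximate_entropy(sin(2 * pi * 10 * t2), cfg),
            approximate_entropy(rnorm(length(t2)), cfg))
  expect_error(approximate_entropy(rnorm(20), cfg), "50")
})

test_that("LZ76 phrase counting matches the classic parse and the oracle", {
  bits <- c(0, 0, 0, 1, 1, 0, 1, 0, 0, 1, 0, 0, 0, 1, 0, 1)
  # hand parse: 0 | 001 | 10 | 100 | 1000 | 101 -> 6 phrases
  expect_equal(eegdepth:::lz76_count(bits), 6L)
  expect_equal(lz76_oracle(bits), 6L)

  set.seed(7)
  for (i in 1:10) {
    b <- sample(0:1, 64, replace = TRUE)
    expect_equal(eegdepth:::lz76_count(b), lz76_oracle(b))
  }
})

test_that("normalized LZ complexity: periodic signals fall, random stay near 1", {
  cfg <- entropy_config()
  t_long <- seq(0, 32, by = 1 / fs)
  per_short <- lempel_ziv_complexity(sin(2 * pi * 8 * t_long[1:512]), cfg)
  per_long <- lempel_ziv_complexity(sin(2 * pi * 8 * t_long), cfg)
  expect_lt(per_long, per_short)
  expect_lt(per_long, 0.15)

  set.seed(8)
  expect_gt(lempel_ziv_complexity(rnorm(4096), cfg), 0.7)
})

test_that("wavelet characteristic reflects subband energy concentration", {
  cfg <- entropy_config()
  # 3 Hz tone lives in the level-4 approximation band (0-4 Hz)
  tone3 <- sin(2 * pi * 3 * seq(0, 2 - 1 / fs, by = 1 / fs))
  expect_lt(wavelet_characteristic(tone3, cfg), 1)

  # white noise splits energy dyadically: p = (1/2, 1/4, 1/8, 1/16, 1/16)
  p_dyadic <- c(1 / 2, 1 / 4, 1 / 8, 1 / 16, 1 / 16)
  h_expected <- -sum(p_dyadic * log2(p_dyadic))
  set.seed(9)
  h_wn <- mean(replicate(20, wavelet_characteristic(rnorm(4096), cfg)))
  expect_lt(abs(h_wn - h_expected), 0.15)

  expect_equal(wavelet_characteristic(rep(0, 256), cfg), 0)
  for (i in 1:5) {
    expect_lte(wavelet_characteristic(rnorm(256), cfg),
               log2(cfg$wavelet_levels + 1) + 1e-9)
  }
})

test_that("entropy medians fall with anesthetic depth on the default classes", {
  feats <- default_study_features()
  for (f in c("AE", "SE")) {
    med <- tapply(feats[[f]], feats$label, median)
    expect_gt(med[["AWAKE"]], med[["DEEP"]])
    expect_gt(med[["DEEP"]], med[["ISOELECTRIC"]])
  }
})
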