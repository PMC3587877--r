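# The synthetic generator: determinism, spectral shaping, suppression
# realization, and class structure.

test_that("default state specs encode the qualitative depth-of-anesthesia picture", {
  specs <- default_state_specs()
  expect_named(specs, anesthesia_states())
  expect_gt(specs$DEEP$band_gains[["delta"]], specs$DEEP$band_gains[["beta"]])
  expect_gt(specs$AWAKE$band_gains[["beta"]], specs$AWAKE$band_gains[["delta"]])
  expect_gt(specs$ISOELECTRIC$suppression_fraction, specs$DEEP$suppression_fraction)
  expect_identical(specs$AWAKE$suppression_fraction, 0)
  expect_identical(specs$LIGHT$suppression_fraction, 0)
})

test_that("simulation is bit-identical under a fixed seed and changes with it", {
  cfg <- sim_config(duration_s_per_class = 10, seed = 7)
  spec <- default_state_specs()$DEEP
  r1 <- simulate_class(spec, cfg)
  r2 <- simulate_class(spec, cfg)
  expect_identical(r1$samples, r2$samples)
  r3 <- simulate_class(spec, sim_config(duration_s_per_class = 10, seed = 8))
  expect_false(identical(r1$samples, r3$samples))
})

test_that("spectral shaping puts the PSD maximum in the dominant band", {
  cfg <- sim_config(duration_s_per_class = 30, seed = 3)
  deep <- simulate_class(default_state_specs()$DEEP, cfg)
  psd <- welch_psd(deep$samples, cfg$fs_hz, spectral_config(segment_s = 2))
  f_peak <- psd$freqs_hz[which.max(psd$power)]
  edges <- eeg_band_edges()$delta
  expect_gte(f_peak, edges[1] - 0.5)
  expect_lte(f_peak, edges[2])

  awake <- simulate_class(default_state_specs()$AWAKE, cfg)
  psd_a <- welch_psd(awake$samples, cfg$fs_hz)
  bp <- band_powers(psd_a)
  expect_gt(bp$ratio[bp$band == "beta"], bp$ratio[bp$band == "delta"])
})

test_that("fully suppressed signal with vanishing floor has vanishing RMS", {
  spec <- state_spec("ISOELECTRIC",
                     band_gains = c(delta = 1, theta = 0, alpha = 0, beta = 0),
                     amplitude_uV = 2, suppression_fraction = 1)
  cfg <- sim_config(duration_s_per_class = 5, noise_floor_uV = 1e-6)
  rec <- simulate_class(spec, cfg)
  expect_lt(sqrt(mean(rec$samples^2)), 1e-5)
})

test_that("simulate_study concatenates four labelled segments in canonical order", {
  cfg <- sim_config(duration_s_per_class = 60, seed = 2)
  rec <- simulate_study(cfg)
  expect_equal(record_duration(rec), 240)
  expect_equal(nrow(rec$segments), 4)
  expect_identical(rec$segments$label, anesthesia_states())
  expect_equal(rec$segments$end_s - rec$segments$start_s, rep(60, 4))

  rec2 <- simulate_study(sim_config(duration_s_per_class = 60, seed = 3))
  expect_false(identical(rec$samples, rec2$samples))
  expect_identical(rec$segments, rec2$segments)
})

test_that("missing classes and too-short durations are rejected by name", {
  specs <- default_state_specs()
  expect_error(simulate_study(sim_config(), specs[c("AWAKE", "LIGHT")]),
               "DEEP")
  expect_error(simulate_class(specs$AWAKE, sim_config(duration_s_per_class = 1)),
               "epoch")
})

test_that("realized isoelectric suppression matches its spec within 0.05", {
  cfg <- sim_config(duration_s_per_class = 60, seed = 5)
  spec <- default_state_specs()$ISOELECTRIC
  rec <- simulate_class(spec, cfg)
  mask <- detect_suppression(rec$samples, cfg$fs_hz)
  realized <- mean(unclass(mask))
  expect_lt(abs(realized - spec$suppression_fraction), 0.05)
})

test_that("entropy-quadruple scatter separates classes (within < between)", {
  feats <- default_study_features()
  sub <- c("AE", "L-Z V", "RE(3)", "SE")
  Z <- scale(as.matrix(feats[, sub]))
  centroids <- apply(Z, 2, function(col) tapply(col, feats$label, mean))
  within <- mean(vapply(anesthesia_states(), function(cls) {
    rows <- feats$label == cls
    mean(rowSums(sweep(Z[rows, , drop = FALSE], 2, centroids[cls, ])^2))
  }, 0))
  global <- colMeans(Z)
  between <- mean(rowSums(sweep(centroids, 2, global)^2))
  expect_lt(within, between)
})
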