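# Synthetic anesthesia-EEG generator: band-filtered white-noise mixtures
# gated by a stochastic burst/suppression envelope.

# Band-limited unit-RMS noise; 4th-order Butterworth band-pass on white noise.
band_noise <- function(n, fs, lo, hi) {
  nyq <- fs / 2
  bf <- signal::butter(4, c(lo, hi) / nyq, type = "pass")
  x <- signal::filter(bf, rnorm(n + fs))       # one extra second warm-up
  x <- x[(fs + 1):(fs + n)]
  x / sqrt(mean(x^2))
}

# Residual-activity floor: slow (low-pass) noise, unit RMS. Suppressed and
# isoelectric EEG is not broadband instrument noise but low-amplitude slow
# residual activity, so the floor is band-limited in the sub-delta range.
floor_noise <- function(n, fs, cutoff_hz = 1.5) {
  bf <- signal::butter(2, cutoff_hz / (fs / 2), type = "low")
  x <- signal::filter(bf, rnorm(n + fs))
  x <- x[(fs + 1):(fs + n)]
  x / sqrt(mean(x^2))
}

# Alternating burst/suppression envelope (1 = burst, 0 = suppressed).
# Episode durations: shifted exponentials, suppression capped at max_s.
suppression_envelope <- function(n, fs, spec) {
  f <- spec$suppression_fraction
  if (f <= 0) return(rep(1, n))
  if (f >= 1) return(rep(0, n))
  cycle <- 1 / spec$burst_rate_hz
  mean_supp <- f * cycle
  mean_burst <- (1 - f) * cycle
  min_s <- spec$min_suppression_s
  if (mean_supp <= min_s) min_s <- 0.8 * mean_supp
  min_b <- spec$min_burst_s
  if (mean_burst <= min_b) min_b <- 0.8 * mean_burst
  env <- numeric(0)
  state <- runif(1) < f  # TRUE = start suppressed
  while (length(env) < n) {
    if (state) {
      dur <- min_s + rexp(1, rate = 1 / max(mean_supp - min_s, 1e-3))
      dur <- min(dur, spec$max_suppression_s)
      env <- c(env, rep(0, max(1L, round(dur * fs))))
    } else {
      dur <- min_b + rexp(1, rate = 1 / max(mean_burst - min_b, 1e-3))
      dur <- min(dur, spec$max_burst_s)
      env <- c(env, rep(1, max(1L, round(dur * fs))))
    }
    state <- !state
  }
  env[seq_len(n)]
}

#' Simulate one anesthesia-state EEG segment
#'
#' Generates a single-channel EEG signal realizing the spectral and
#' burst-suppression profile of one anesthesia class: white noise is
#' band-pass filtered into the four classical bands, mixed with the spec's
#' relative band weights, gated by a burst/suppression envelope, scaled so
#' the overall RMS meets `amplitude_uV`, and overlaid with the white noise
#' floor. Identical `(spec, cfg)` (including `cfg$seed`) gives bit-identical
#' samples.
#'
#' @param spec A [state_spec()].
#' @param cfg A [sim_config()].
#'
#' @return An [eeg_record()] with one labelled segment.
#' @export
#' @examples
#' rec <- simulate_class(default_state_specs()$DEEP, sim_config(duration_s_per_class = 10))
#' rec
simulate_class <- function(spec, cfg) {
  stopifnot(inherits(spec, "state_spec"), inherits(cfg, "sim_config"))
  if (cfg$duration_s_per_class < 2) {
    abort("duration_s_per_class too short: need at least one 2-s analysis epoch.")
  }
  n <- round(cfg$fs_hz * cfg$duration_s_per_class)
  class_idx <- match(spec$label, anesthesia_states())
  x <- with_seed(cfg$seed + class_idx, {
    edges <- eeg_band_edges()
    w <- spec$band_gains / sum(spec$band_gains)
    shaped <- numeric(n)
    for (b in names(w)) {
      if (w[[b]] > 0) {
        shaped <- shaped +
          sqrt(w[[b]]) * band_noise(n, cfg$fs_hz, edges[[b]][1], edges[[b]][2])
      }
    }
    shaped <- shaped / sqrt(mean(shaped^2))

    env <- suppression_envelope(n, cfg$fs_hz, spec)
    # Burst amplitude chosen so the segment RMS hits amplitude_uV overall:
    # RMS^2 = (1 - f) * A_burst^2 + noise_floor^2.
    f <- mean(env == 0)
    a2 <- (spec$amplitude_uV^2 - cfg$noise_floor_uV^2) / max(1 - f, 1e-12)
    a_burst <- sqrt(max(a2, 0))
    a_burst * env * shaped + cfg$noise_floor_uV * floor_noise(n, cfg$fs_hz)
  })

  eeg_record(
    samples = x,
    fs_hz = cfg$fs_hz,
    segments = tibble(
      start_s = 0, end_s = n / cfg$fs_hz, label = spec$label
    )
  )
}

#' Simulate a full four-class reference study
#'
#' Concatenates one labelled segment per anesthesia class (canonical order
#' awake, light, deep, isoelectric), each of `cfg$duration_s_per_class`
#' seconds, into a single record with segment boundary metadata — the
#' synthetic analogue of a reference recording with equal time per class.
#'
#' @param cfg A [sim_config()].
#' @param specs Named list of [state_spec()]s covering all four classes;
#'   defaults to [default_state_specs()].
#'
#' @return An [eeg_record()] with four labelled segments.
#' @export
#' @examples
#' rec <- simulate_study(sim_config(duration_s_per_class = 10))
#' rec$segments
simulate_study <- function(cfg = sim_config(), specs = default_state_specs()) {
  states <- anesthesia_states()
  missing <- setdiff(states, names(specs))
  if (length(missing) > 0) {
    abort(sprintf("Missing state spec(s): %s.", paste(missing, collapse = ", ")))
  }
  recs <- lapply(states, function(s) simulate_class(specs[[s]], cfg))
  seg_len <- cfg$duration_s_per_class
  samples <- unlist(lapply(recs, function(r) r$samples), use.names = FALSE)
  segments <- tibble(
    start_s = seg_len * (seq_along(states) - 1),
    end_s = seg_len * seq_along(states),
    label = states
  )
  eeg_record(samples, cfg$fs_hz, segments)
}
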