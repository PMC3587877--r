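#' Define an anesthesia-state spectral/suppression specification
#'
#' A `state_spec` describes how one anesthesia class is synthesized: the
#' relative power placed in each classical EEG band, the target RMS amplitude,
#' and the burst-suppression envelope (fraction of time suppressed and the
#' rate of burst onsets). Band weights are relative: they are normalized to
#' sum to one at simulation time.
#'
#' Suppression is modelled as an alternating burst/suppression envelope with
#' stochastic episode durations. `min_suppression_s` and `max_suppression_s`
#' bound a suppression episode; the mean episode lengths are derived from
#' `suppression_fraction` and `burst_rate_hz` (one burst onset per cycle, so
#' the mean cycle is `1 / burst_rate_hz`).
#'
#' @param label One of `anesthesia_states()`.
#' @param band_gains Named numeric vector with entries `delta`, `theta`,
#'   `alpha`, `beta`: non-negative relative band power weights, not all zero.
#' @param amplitude_uV Target overall RMS amplitude of the segment in
#'   microvolts (must be positive). During suppression the signal falls to
#'   the simulation noise floor; burst amplitude is scaled up so the overall
#'   RMS still meets this target.
#' @param suppression_fraction Fraction of time spent suppressed, in `[0, 1]`.
#' @param burst_rate_hz Burst onsets per second (used only when
#'   `suppression_fraction > 0`).
#' @param min_suppression_s,max_suppression_s Bounds on a single suppression
#'   episode duration in seconds.
#' @param min_burst_s,max_burst_s Bounds on a single burst episode duration
#'   in seconds.
#'
#' @return An object of class `state_spec`.
#' @seealso [default_state_specs()], [simulate_class()]
#' @export
state_spec <- function(label,
                       band_gains,
                       amplitude_uV,
                       suppression_fraction = 0,
                       burst_rate_hz = 0.3,
                       min_suppression_s = 0.55,
                       max_suppression_s = Inf,
                       min_burst_s = 0.1,
                       max_burst_s = Inf) {
  assert_state(label)
  bands <- c("delta", "theta", "alpha", "beta")
  if (!all(bands %in% names(band_gains))) {
    abort("band_gains must be named with delta, theta, alpha, beta.")
  }
  band_gains <- band_gains[bands]
  if (any(band_gains < 0) || all(band_gains == 0)) {
    abort("band_gains must be non-negative and not all zero.")
  }
  if (!is.numeric(amplitude_uV) || amplitude_uV <= 0) {
    abort("amplitude_uV must be positive.")
  }
  if (suppression_fraction < 0 || suppression_fraction > 1) {
    abort("suppression_fraction must lie in [0, 1].")
  }
  structure(
    list(
      label = label,
      band_gains = band_gains,
      amplitude_uV = amplitude_uV,
      suppression_fraction = suppression_fraction,
      burst_rate_hz = burst_rate_hz,
      min_suppression_s = min_suppression_s,
      max_suppression_s = max_suppression_s,
      min_burst_s = min_burst_s,
      max_burst_s = max_burst_s
    ),
    class = "state_spec"
  )
}

#' @export
print.state_spec <- function(x, ...) {
  cat(sprintf(
    "<state_spec %s> RMS %.1f uV, suppression %.2f, gains: %s\n",
    x$label, x$amplitude_uV, x$suppression_fraction,
    paste(sprintf("%s=%.2f", names(x$band_gains), x$band_gains), collapse = " ")
  ))
  invisible(x)
}

#' Default specifications for the four reference anesthesia classes
#'
#' Encodes the canonical qEEG picture of deepening anesthesia: the awake EEG
#' is low-amplitude and beta-dominant; light anesthesia shifts power into
#' alpha/theta with growing amplitude; deep anesthesia is high-amplitude,
#' delta-dominant with intermittent burst suppression; the isoelectric
#' (brain-death reference) state is near the noise floor and suppressed
#' almost all of the time.
#'
#' Deep-state suppression episodes are capped below one 2-s analysis epoch so
#' that every deep epoch retains some slow-wave burst activity; isoelectric
#' suppression episodes are uncapped (long flat stretches with brief
#' low-amplitude bursts).
#'
#' @return Named list of four [state_spec()] objects, one per state, in
#'   canonical order.
#' @export
#' @examples
#' specs <- default_state_specs()
#' specs$DEEP
default_state_specs <- function() {
  list(
    AWAKE = state_spec(
      "AWAKE",
      band_gains = c(delta = 0.05, theta = 0.10, alpha = 0.20, beta = 0.65),
      amplitude_uV = 10, suppression_fraction = 0
    ),
    LIGHT = state_spec(
      "LIGHT",
      band_gains = c(delta = 0.20, theta = 0.50, alpha = 0.27, beta = 0.03),
      amplitude_uV = 20, suppression_fraction = 0
    ),
    DEEP = state_spec(
      "DEEP",
      band_gains = c(delta = 0.75, theta = 0.15, alpha = 0.08, beta = 0.02),
      amplitude_uV = 40, suppression_fraction = 0.40,
      burst_rate_hz = 0.65, max_suppression_s = 0.8,
      min_burst_s = 0.75, max_burst_s = 1.0
    ),
    ISOELECTRIC = state_spec(
      "ISOELECTRIC",
      band_gains = c(delta = 0.70, theta = 0.15, alpha = 0.10, beta = 0.05),
      amplitude_uV = 2, suppression_fraction = 0.98,
      burst_rate_hz = 0.05
    )
  )
}

#' Simulation configuration
#'
#' @param fs_hz Sampling rate in Hz; must be at least 100 so the 47 Hz
#'   analysis ceiling stays below Nyquist. Default 128.
#' @param duration_s_per_class Seconds simulated per anesthesia class.
#' @param seed Integer RNG seed; fixed seed gives bit-identical signals.
#' @param noise_floor_uV RMS in microvolts of the additive residual-activity
#'   floor (slow, band-limited noise present everywhere; also the level a
#'   suppressed signal falls to).
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(fs_hz = 128,
                       duration_s_per_class = 60,
                       seed = 1L,
                       noise_floor_uV = 1) {
  if (fs_hz < 100) abort("fs_hz must be >= 100 (analysis ceiling is 47 Hz).")
  if (duration_s_per_class <= 0) abort("duration_s_per_class must be positive.")
  if (noise_floor_uV < 0) abort("noise_floor_uV must be non-negative.")
  structure(
    list(
      fs_hz = fs_hz,
      duration_s_per_class = duration_s_per_class,
      seed = as.integer(seed),
      noise_floor_uV = noise_floor_uV
    ),
    class = "sim_config"
  )
}
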