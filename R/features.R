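# Assembling the per-epoch feature matrix: 19 quantitative EEG
# characteristics plus the BIS-style beta log-ratio.

#' Canonical feature names
#'
#' The registry of extracted characteristics, using the field's standard
#' abbreviations: spectral edge frequency (SEF), median frequency (MF),
#' absolute delta/theta/alpha/beta band powers (DBP, TBP, ABP, BBP),
#' relative alpha/beta/theta band-power ratios (ARF, BRF, TRF), the
#' bispectral SynchFastSlow ratio (BSFSR), burst suppression percent
#' (BS%), Shannon entropy (ShE), spectral entropy (SE), Renyi entropies of
#' order -1 and 3 (RE(-1), RE(3)), singular-value-decomposition entropy
#' (SVDE), approximate entropy (AE), Lempel-Ziv complexity (L-Z V), the
#' wavelet-energy characteristic (WBC), and the BIS beta log-ratio
#' (BetaRatioBIS).
#'
#' @param pool One of `"all"`, `"entropy"` (the seven entropy/complexity
#'   characteristics plus WBC), or `"frequency"` (spectral features + BS%).
#' @return Character vector of feature names.
#' @export
feature_names <- function(pool = c("all", "entropy", "frequency")) {
  pool <- match.arg(pool)
  switch(pool,
    all = c(
      "SEF", "MF", "DBP", "TBP", "ABP", "BBP", "ARF", "BRF", "TRF",
      "BSFSR", "BS%", "ShE", "SE", "RE(-1)", "RE(3)", "SVDE", "AE",
      "L-Z V", "WBC", "BetaRatioBIS"
    ),
    entropy = c("ShE", "SE", "RE(-1)", "RE(3)", "SVDE", "AE", "L-Z V", "WBC"),
    frequency = c(
      "SEF", "MF", "DBP", "TBP", "ABP", "BBP", "ARF", "BRF", "TRF",
      "BS%", "BetaRatioBIS"
    )
  )
}

#' Extract the quantitative EEG characteristics for every epoch
#'
#' Computes all registered characteristics per epoch: Welch-PSD-derived
#' spectral features, the burst suppression ratio, the bispectral
#' SynchFastSlow ratio, and the entropy/complexity family. Features that
#' are undefined on an epoch (e.g. ratios of a zero-power spectrum) are
#' `NA`.
#'
#' @param epochs An [epochize()] tibble.
#' @param entropy_cfg An [entropy_config()].
#' @param spectral_cfg A [spectral_config()] for the Welch PSD.
#' @param bispectral_cfg A [spectral_config()] for bispectrum averaging;
#'   the default (0.5 s segments, 75% overlap) yields 13 averaging
#'   segments on a 2 s epoch.
#' @param bsr_threshold_uV,bsr_min_ms Suppression-detection parameters, see
#'   [detect_suppression()].
#'
#' @return Tibble with `epoch`, `label`, `start_s` and one column per
#'   feature in [feature_names()].
#' @export
#' @examples
#' rec <- simulate_study(sim_config(duration_s_per_class = 10))
#' feats <- extract_features(epochize(rec))
#' dplyr::glimpse(feats)
extract_features <- function(epochs,
                             entropy_cfg = entropy_config(),
                             spectral_cfg = spectral_config(),
                             bispectral_cfg = spectral_config(segment_s = 0.5, overlap = 0.75),
                             bsr_threshold_uV = 5,
                             bsr_min_ms = 500) {
  stopifnot(is_tibble(epochs), all(c("samples", "label", "fs_hz") %in% names(epochs)))
  one <- function(x, fs) {
    psd <- welch_psd(x, fs, spectral_cfg)
    bp <- band_powers(psd)
    pw <- setNames(bp$power_uV2, bp$band)
    rt <- setNames(bp$ratio, bp$band)
    bsp <- bispectrum(x, fs, bispectral_cfg)
    mask <- detect_suppression(x, fs, bsr_threshold_uV, bsr_min_ms)
    tibble(
      "SEF" = spectral_edge_frequency(psd),
      "MF" = median_frequency(psd),
      "DBP" = pw[["delta"]],
      "TBP" = pw[["theta"]],
      "ABP" = pw[["alpha"]],
      "BBP" = pw[["beta"]],
      "ARF" = rt[["alpha"]],
      "BRF" = rt[["beta"]],
      "TRF" = rt[["theta"]],
      "BSFSR" = synch_fast_slow(bsp),
      "BS%" = bsr(mask),
      "ShE" = shannon_entropy(x, entropy_cfg),
      "SE" = spectral_entropy(psd),
      "RE(-1)" = renyi_entropy(x, -1, entropy_cfg),
      "RE(3)" = renyi_entropy(x, 3, entropy_cfg),
      "SVDE" = svd_entropy(x, entropy_cfg),
      "AE" = approximate_entropy(x, entropy_cfg),
      "L-Z V" = lempel_ziv_complexity(x, entropy_cfg),
      "WBC" = wavelet_characteristic(x, entropy_cfg),
      "BetaRatioBIS" = beta_ratio_bis(psd)
    )
  }
  vals <- purrr::map2(epochs$samples, epochs$fs_hz, one)
  feats <- dplyr::bind_rows(vals)
  dplyr::bind_cols(
    epochs[, c("epoch", "label", "start_s")],
    feats[, feature_names("all")]
  )
}
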