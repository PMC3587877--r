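# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_tile geom_text
#'   geom_boxplot geom_col scale_fill_gradient labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Plot an EEG record
#'
#' Trace of the signal coloured by anesthesia-state segment.
#'
#' @param object An [eeg_record()].
#' @param max_points Down-sampling cap for long records.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eeg_record <- function(object, max_points = 20000, ...) {
  df <- as_tibble(object)
  if (nrow(df) > max_points) {
    df <- df[seq(1, nrow(df), length.out = max_points), ]
  }
  ggplot(df, aes(x = .data$time_s, y = .data$amplitude_uV, colour = .data$label)) +
    geom_line(linewidth = 0.3) +
    labs(x = "Time (s)", y = "Amplitude (uV)", colour = "State") +
    theme_minimal()
}

#' Plot a Welch PSD estimate
#'
#' @param object A [welch_psd()] result.
#' @param ... Unused.
#' @return A ggplot object (log10 power vs frequency, 0.5-47 Hz).
#' @export
autoplot.psd_estimate <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[df$freq_hz >= 0.5 & df$freq_hz <= 47, ]
  ggplot(df, aes(x = .data$freq_hz, y = .data$power_uV2_hz)) +
    geom_line() +
    ggplot2::scale_y_log10() +
    labs(x = "Frequency (Hz)", y = "PSD (uV^2/Hz)") +
    theme_minimal()
}

#' Plot a classification report as a confusion heatmap
#'
#' @param object A [evaluate_classification()] report.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.classification_report <- function(object, ...) {
  cm <- object$confusion
  df <- as.data.frame.table(cm, responseName = "count")
  names(df)[1:2] <- c("truth", "predicted")
  ggplot(df, aes(x = .data$predicted, y = .data$truth, fill = .data$count)) +
    geom_tile() +
    geom_text(aes(label = .data$count)) +
    scale_fill_gradient(low = "white", high = "steelblue") +
    labs(
      x = "Predicted state", y = "True state",
      title = sprintf("Total accuracy %.2f%%", object$accuracy)
    ) +
    theme_minimal()
}

#' Plot a GA convergence history
#'
#' @param object A [run_ga()] result.
#' @param ... Unused.
#' @return A ggplot object of best classification error per generation.
#' @export
autoplot.ga_result <- function(object, ...) {
  ggplot(object$history, aes(x = .data$generation, y = .data$best_fitness)) +
    geom_line() +
    labs(
      x = "Generation", y = "Best classification error",
      title = sprintf("GA k=%d: best {%s}", object$config$k,
                      paste(object$best_features, collapse = ", "))
    ) +
    theme_minimal()
}

#' Boxplots of feature distributions by anesthesia state
#'
#' @param features A feature tibble from [extract_features()].
#' @param which Feature names to show (default: the entropy family).
#' @return A ggplot object, one facet per feature (free y scales).
#' @export
plot_feature_distributions <- function(features, which = feature_names("entropy")) {
  long <- tidyr::pivot_longer(
    features[, c("label", which)],
    cols = dplyr::all_of(which),
    names_to = "feature", values_to = "value"
  )
  long$label <- factor(long$label, levels = anesthesia_states())
  ggplot(long, aes(x = .data$label, y = .data$value, fill = .data$label)) +
    geom_boxplot(show.legend = FALSE) +
    facet_wrap(~feature, scales = "free_y") +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}

#' Bar chart of single-feature accuracies from a study
#'
#' @param study An [run_study()] result.
#' @return A ggplot object sorted by accuracy.
#' @export
plot_single_feature_accuracy <- function(study) {
  df <- dplyr::select(study$single_features, "feature", "accuracy")
  df$feature <- stats::reorder(df$feature, df$accuracy)
  ggplot(df, aes(x = .data$feature, y = .data$accuracy)) +
    geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    labs(x = NULL, y = "Cross-validated accuracy (%)") +
    theme_minimal()
}
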