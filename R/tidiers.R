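# broom-style tidiers for fitted objects and reports.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a classification report
#'
#' @param x A [evaluate_classification()] report.
#' @param ... Unused.
#' @return Tibble with one row per class: `class`, `n`, `sensitivity`,
#'   `specificity`.
#' @export
tidy.classification_report <- function(x, ...) {
  x$per_class
}

#' One-row summary of a classification report
#'
#' @param x A [evaluate_classification()] report.
#' @param ... Unused.
#' @return Tibble with `accuracy` (%), `n`, and the macro-averaged
#'   sensitivity and specificity.
#' @export
glance.classification_report <- function(x, ...) {
  tibble(
    accuracy = x$accuracy,
    n = x$n,
    mean_sensitivity = mean(x$per_class$sensitivity, na.rm = TRUE),
    mean_specificity = mean(x$per_class$specificity, na.rm = TRUE)
  )
}

#' Tidy a fitted anesthesia classifier
#'
#' @param x A [fit_state_classifier()] model.
#' @param ... Unused.
#' @return Tibble with one row per class and feature: the class-conditional
#'   mean and variance in z-scored feature space, plus the class prior.
#' @export
tidy.anesthesia_classifier <- function(x, ...) {
  purrr::imap_dfr(x$class_models, function(m, cls) {
    tibble(
      class = cls,
      feature = x$subset,
      mean = unname(m$mean),
      variance = unname(diag(m$cov)),
      prior = m$prior
    )
  })
}

#' One-row summary of a fitted anesthesia classifier
#'
#' @param x A [fit_state_classifier()] model.
#' @param ... Unused.
#' @return Tibble with the subset size, its features, and training size.
#' @export
glance.anesthesia_classifier <- function(x, ...) {
  tibble(
    n_features = length(x$subset),
    features = paste(x$subset, collapse = " / "),
    n_train = x$n_train,
    n_classes = length(x$classes)
  )
}

#' Tidy a GA search result
#'
#' @param x A [run_ga()] result.
#' @param ... Unused.
#' @return The per-generation best-fitness history tibble.
#' @export
tidy.ga_result <- function(x, ...) {
  x$history
}

#' One-row summary of a GA search result
#'
#' @param x A [run_ga()] result.
#' @param ... Unused.
#' @return Tibble with the winning subset, its accuracy, and search size.
#' @export
glance.ga_result <- function(x, ...) {
  tibble(
    k = x$config$k,
    features = paste(x$best_features, collapse = " / "),
    accuracy = x$best_accuracy,
    error = x$best_fitness,
    n_evaluations = x$n_evaluations,
    generations = x$config$generations
  )
}
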