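# Gaussian class-conditional (quadratic discriminant) classifier over
# z-scored feature subsets, with confusion-matrix reporting and stratified
# cross-validation.

# Evaluate code with a local seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

check_subset <- function(subset, available) {
  if (length(subset) == 0) abort("Feature subset must be non-empty.")
  bad <- setdiff(subset, available)
  if (length(bad) > 0) {
    abort(sprintf(
      "Unknown feature(s): %s. Valid features are: %s.",
      paste(bad, collapse = ", "), paste(available, collapse = ", ")
    ))
  }
  invisible(subset)
}

#' Fit a Gaussian class-conditional anesthesia-state classifier
#'
#' Fits one multivariate Gaussian per anesthesia state on the z-scored
#' feature subset (a quadratic discriminant rule with class-specific
#' covariances and empirical priors). Z-scoring statistics come from the
#' training rows only. Rows with a missing (sentinel) value in the subset
#' are excluded with a message. A near-singular class covariance is
#' ridge-regularized with a warning.
#'
#' @param features A feature tibble from [extract_features()] with a
#'   `label` column.
#' @param subset Character vector of feature names to use.
#' @param ridge Initial ridge added to a non-positive-definite covariance,
#'   as a fraction of the mean diagonal.
#'
#' @return An object of class `anesthesia_classifier`.
#' @export
fit_state_classifier <- function(features, subset, ridge = 1e-6) {
  avail <- setdiff(names(features), c("epoch", "label", "start_s"))
  check_subset(subset, avail)
  X <- as.matrix(features[, subset, drop = FALSE])
  keep <- stats::complete.cases(X)
  if (any(!keep)) {
    inform(sprintf("fit_state_classifier: excluded %d row(s) with missing feature values.",
                   sum(!keep)))
  }
  X <- X[keep, , drop = FALSE]
  y <- features$label[keep]
  assert_state(y)
  states <- anesthesia_states()
  missing_cls <- setdiff(states, unique(y))
  if (length(missing_cls) > 0) {
    abort(sprintf("Training data lacks class(es): %s.",
                  paste(missing_cls, collapse = ", ")))
  }
  mu <- colMeans(X)
  sig <- apply(X, 2, sd)
  sig[sig == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sig, "/")

  fit_class <- function(cls) {
    Zi <- Z[y == cls, , drop = FALSE]
    m <- colMeans(Zi)
    S <- stats::cov(Zi)
    lambda <- 0
    repeat {
      Sl <- S + lambda * diag(ncol(S))
      ok <- tryCatch(rcond(Sl) > 1e-12, error = function(e) FALSE)
      if (isTRUE(ok)) break
      lambda <- if (lambda == 0) max(ridge * mean(diag(S)), 1e-10) else lambda * 10
      if (lambda > 1e6 * max(mean(diag(S)), 1)) {
        abort("Covariance regularization failed.")
      }
    }
    if (lambda > 0) {
      warn(sprintf("Near-singular covariance for class %s; ridge %.3g added.", cls, lambda))
      S <- S + lambda * diag(ncol(S))
    }
    list(
      mean = m,
      cov = S,
      inv = solve(S),
      logdet = as.numeric(determinant(S, logarithm = TRUE)$modulus),
      prior = mean(y == cls)
    )
  }
  structure(
    list(
      subset = subset,
      norm = list(mean = mu, sd = sig),
      classes = states,
      class_models = setNames(lapply(states, fit_class), states),
      n_train = nrow(Z)
    ),
    class = "anesthesia_classifier"
  )
}

#' @export
print.anesthesia_classifier <- function(x, ...) {
  cat(sprintf(
    "<anesthesia_classifier> QDA on {%s}, %d training epochs, priors: %s\n",
    paste(x$subset, collapse = ", "), x$n_train,
    paste(sprintf("%s=%.2f", x$classes,
                  vapply(x$class_models, function(m) m$prior, 0)), collapse = " ")
  ))
  invisible(x)
}

#' Predict anesthesia states for new epochs
#'
#' Assigns each row the state with maximal Gaussian log-posterior. Ties are
#' broken by the fixed canonical class order (awake < light < deep <
#' isoelectric). Rows with missing subset values receive `NA` and are
#' reported.
#'
#' @param object An [fit_state_classifier()] model.
#' @param newdata Feature tibble containing the model's subset columns.
#' @param ... Unused.
#' @return Character vector of predicted state labels.
#' @export
predict.anesthesia_classifier <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$subset, drop = FALSE])
  keep <- stats::complete.cases(X)
  out <- rep(NA_character_, nrow(X))
  if (any(!keep)) {
    inform(sprintf("predict: %d row(s) with missing feature values left unclassified.",
                   sum(!keep)))
  }
  if (!any(keep)) return(out)
  Z <- sweep(sweep(X[keep, , drop = FALSE], 2, object$norm$mean), 2,
             object$norm$sd, "/")
  scores <- sapply(object$classes, function(cls) {
    m <- object$class_models[[cls]]
    D <- sweep(Z, 2, m$mean)
    q <- rowSums((D %*% m$inv) * D)
    log(m$prior) - 0.5 * m$logdet - 0.5 * q
  })
  scores <- matrix(scores, ncol = length(object$classes))
  out[keep] <- object$classes[max.col(scores, ties.method = "first")]
  out
}

#' Confusion-matrix classification report
#'
#' Builds the 4x4 confusion matrix over the anesthesia states and derives
#' per-class sensitivity `TP / (TP + FN)`, per-class specificity
#' `TN / (TN + FP)` (one class against the rest), and total accuracy
#' `100 * trace / total`. Pairs with a missing prediction are dropped with
#' a message.
#'
#' @param truth,predicted Equal-length vectors of state labels.
#' @return An object of class `classification_report`: list with
#'   `confusion` (truth in rows), `per_class` tibble, `accuracy` (%), `n`.
#' @export
evaluate_classification <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    abort("truth and predicted must have equal length.")
  }
  if (length(truth) == 0) abort("Empty label vectors.")
  keep <- !is.na(predicted)
  if (any(!keep)) {
    inform(sprintf("evaluate_classification: dropped %d unclassified row(s).",
                   sum(!keep)))
  }
  truth <- truth[keep]; predicted <- predicted[keep]
  assert_state(truth, "truth"); assert_state(predicted, "predicted")
  states <- anesthesia_states()
  cm <- table(
    factor(truth, levels = states),
    factor(predicted, levels = states)
  )
  cm <- unclass(cm)
  total <- sum(cm)
  per_class <- purrr::map_dfr(states, function(cls) {
    i <- match(cls, states)
    tp <- cm[i, i]
    fn <- sum(cm[i, -i])
    fp <- sum(cm[-i, i])
    tn <- total - tp - fn - fp
    tibble(
      class = cls,
      n = tp + fn,
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_
    )
  })
  structure(
    list(
      confusion = cm,
      per_class = per_class,
      accuracy = 100 * sum(diag(cm)) / total,
      n = total
    ),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> accuracy %.2f%% on %d epochs\n",
              x$accuracy, x$n))
  print(x$confusion)
  print(x$per_class)
  invisible(x)
}

#' Stratified k-fold cross-validated classification
#'
#' Splits epochs into `k` folds stratified by state (deterministically
#' under `seed`), fits the classifier on each training split with
#' fold-internal z-scoring, predicts the held-out fold, and pools all
#' held-out predictions into one [evaluate_classification()] report.
#'
#' @param features Feature tibble with `label`.
#' @param subset Feature names to use.
#' @param k Number of folds (default 5).
#' @param seed RNG seed controlling the fold assignment.
#' @return A `classification_report` for the pooled held-out predictions.
#' @export
#' @examples
#' rec <- simulate_study(sim_config(duration_s_per_class = 12))
#' feats <- extract_features(epochize(rec))
#' cross_validate(feats, c("AE", "SE"))
cross_validate <- function(features, subset, k = 5, seed = 1) {
  avail <- setdiff(names(features), c("epoch", "label", "start_s"))
  check_subset(subset, avail)
  n <- nrow(features)
  fold <- integer(n)
  with_seed(seed, {
    for (cls in unique(features$label)) {
      idx <- which(features$label == cls)
      idx <- sample(idx)
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  truth <- character(0)
  pred <- character(0)
  for (f in seq_len(k)) {
    tr <- features[fold != f, , drop = FALSE]
    te <- features[fold == f, , drop = FALSE]
    model <- fit_state_classifier(tr, subset)
    p <- predict(model, te)
    truth <- c(truth, te$label)
    pred <- c(pred, p)
  }
  evaluate_classification(truth, pred)
}
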