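# End-to-end study orchestration: simulate -> epoch -> extract -> classify
# -> select, with the named composite feature vectors from the monitoring
# literature as fixed presets.

#' Named composite feature vectors
#'
#' Fixed feature subsets mirroring the composite indices discussed in the
#' depth-of-anesthesia literature: the CSI input quadruple (alpha/beta/
#' theta ratios + burst suppression), a BIS-component triple (burst
#' suppression, beta log-ratio, SynchFastSlow), entropy-only quadruple and
#' pentuple, a frequency-domain triple (median frequency, spectral edge,
#' burst suppression), and the approximate-entropy/Shannon/burst-
#' suppression triple.
#'
#' @return Named list of character vectors of feature names.
#' @export
named_vectors <- function() {
  list(
    CSI_QUAD = c("ARF", "BRF", "TRF", "BS%"),
    BIS_TRIPLE = c("BS%", "BetaRatioBIS", "BSFSR"),
    ENTROPY_QUAD = c("AE", "L-Z V", "RE(3)", "SE"),
    ENTROPY_PENT = c("AE", "L-Z V", "RE(3)", "SE", "ShE"),
    BEST_TRIPLE = c("MF", "SEF", "BS%"),
    AE_SHE_BS = c("AE", "ShE", "BS%")
  )
}

#' Run the full synthetic depth-of-anesthesia study
#'
#' Orchestrates the whole pipeline: simulate the four-class study (or use a
#' supplied record), epoch it, screen artifacts, extract all
#' characteristics, evaluate every single feature, every named composite
#' vector, and GA-selected best vectors for each requested dimension —
#' everything cross-validated and reproducible under the seed.
#'
#' @param cfg A [sim_config()] for the synthetic study (ignored when `rec`
#'   is supplied).
#' @param rec Optional [eeg_record()] (e.g. from [read_record()]) to
#'   analyse instead of simulating.
#' @param epoch_s,overlap Epoching parameters, see [epochize()].
#' @param ks GA search dimensions, subset of 2:5.
#' @param cv_folds Cross-validation folds.
#' @param seed Seed for fold assignment and GA search.
#' @param ga_generations,ga_population GA budget per dimension.
#'
#' @return An object of class `anesthesia_study`: list with `features`,
#'   `single_features` (per-feature accuracy tibble), `named_vectors`
#'   (preset accuracies + reports), `ga_best` (per-k winners), and the
#'   parameters used.
#' @export
run_study <- function(cfg = sim_config(),
                      rec = NULL,
                      epoch_s = 2, overlap = 0.5,
                      ks = 2:5,
                      cv_folds = 5,
                      seed = cfg$seed,
                      ga_generations = 60,
                      ga_population = 40) {
  if (is.null(rec)) rec <- simulate_study(cfg)
  epochs <- reject_artifacts(epochize(rec, epoch_s = epoch_s, overlap = overlap))
  inform(sprintf("run_study: %d epochs of %g s extracted from %.0f s of signal.",
                 nrow(epochs), epoch_s, record_duration(rec)))
  features <- extract_features(epochs)
  all_feats <- feature_names("all")

  single <- purrr::map_dfr(all_feats, function(f) {
    rep <- suppressWarnings(suppressMessages(cross_validate(features, f, k = cv_folds, seed = seed)))
    tibble(feature = f, accuracy = rep$accuracy, report = list(rep))
  })
  single <- dplyr::arrange(single, dplyr::desc(.data$accuracy), .data$feature)

  named <- purrr::imap_dfr(named_vectors(), function(sub, nm) {
    rep <- suppressWarnings(suppressMessages(cross_validate(features, sub, k = cv_folds, seed = seed)))
    tibble(
      name = nm, features = paste(sub, collapse = " / "),
      n_features = length(sub), accuracy = rep$accuracy, report = list(rep)
    )
  })

  ga_best <- purrr::map_dfr(ks, function(k) {
    ga <- run_ga(
      features,
      ga_config(k = k, seed = seed, cv_folds = cv_folds,
                generations = ga_generations, population_size = ga_population)
    )
    rep <- suppressWarnings(suppressMessages(
      cross_validate(features, ga$best_features, k = cv_folds, seed = seed)
    ))
    inform(sprintf("run_study: GA k=%d best {%s} accuracy %.2f%%.",
                   k, paste(ga$best_features, collapse = ", "), rep$accuracy))
    tibble(
      k = k, features = paste(ga$best_features, collapse = " / "),
      accuracy = rep$accuracy, report = list(rep), ga = list(ga)
    )
  })

  structure(
    list(
      features = features,
      single_features = single,
      named_vectors = named,
      ga_best = ga_best,
      params = list(
        fs_hz = rec$fs_hz, epoch_s = epoch_s, overlap = overlap,
        cv_folds = cv_folds, seed = seed, ks = ks
      )
    ),
    class = "anesthesia_study"
  )
}

#' @export
print.anesthesia_study <- function(x, ...) {
  cat(sprintf("<anesthesia_study> %d epochs, %d features\n",
              nrow(x$features), length(feature_names("all"))))
  cat("Top single features:\n")
  print(head(dplyr::select(x$single_features, -"report"), 5))
  cat("Named vectors:\n")
  print(dplyr::select(x$named_vectors, -"report"))
  cat("GA winners:\n")
  print(dplyr::select(x$ga_best, -"report", -"ga"))
  invisible(x)
}

#' Compare named feature vectors from a study report
#'
#' @param study An [run_study()] result.
#' @param names Preset names to compare (see [named_vectors()]).
#' @return Tibble sorted by accuracy descending, ties broken by fewer
#'   features.
#' @export
compare_vectors <- function(study, names) {
  if (length(names) == 0) abort("names must be non-empty.")
  known <- study$named_vectors$name
  bad <- setdiff(names, known)
  if (length(bad) > 0) {
    abort(sprintf("Unknown vector name(s): %s. Known: %s.",
                  paste(bad, collapse = ", "), paste(known, collapse = ", ")))
  }
  tab <- study$named_vectors[match(names, known), , drop = FALSE]
  dplyr::arrange(tab, dplyr::desc(.data$accuracy), .data$n_features)
}

#' Serialize a study report to JSON
#'
#' Writes a stable, versioned JSON summary (single-feature accuracies,
#' named-vector and GA-winner accuracies with per-class sensitivity and
#' specificity) suitable for downstream tooling.
#'
#' @param study An [run_study()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_study_json <- function(study, path) {
  report_list <- function(rep) {
    list(
      accuracy = rep$accuracy,
      per_class = rep$per_class,
      confusion = unname(apply(rep$confusion, 1, as.integer, simplify = FALSE))
    )
  }
  payload <- list(
    schema_version = 1L,
    params = study$params,
    single_features = dplyr::select(study$single_features, -"report"),
    named_vectors = purrr::pmap(
      dplyr::select(study$named_vectors, "name", "features", "accuracy", "report"),
      function(name, features, accuracy, report) {
        c(list(name = name, features = features), report_list(report))
      }
    ),
    ga_best = purrr::pmap(
      dplyr::select(study$ga_best, "k", "features", "accuracy", "report"),
      function(k, features, accuracy, report) {
        c(list(k = k, features = features), report_list(report))
      }
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
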