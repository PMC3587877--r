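# Genetic-algorithm search over fixed-dimension feature subsets, with an
# exhaustive-enumeration oracle and per-dimension ranking.

#' Genetic-algorithm configuration
#'
#' The chromosome is a distinct-index subset of fixed dimension `k` (the
#' search is over which `k` features to combine, not over `k` itself).
#' Fitness is the cross-validated classification error `1 - accuracy/100`.
#'
#' @param k Subset dimension, one of 2:5.
#' @param population_size Individuals per generation (>= 4).
#' @param generations Number of generations.
#' @param crossover_rate,mutation_rate Operator probabilities in `[0, 1]`.
#' @param elitism_count Top individuals copied unchanged each generation.
#' @param tournament_size Tournament size for parent selection.
#' @param seed RNG seed; fixed seed gives identical runs.
#' @param cv_folds Cross-validation folds used inside the fitness.
#'
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(k = 4,
                      population_size = 40,
                      generations = 60,
                      crossover_rate = 0.8,
                      mutation_rate = 0.1,
                      elitism_count = 2,
                      tournament_size = 3,
                      seed = 1L,
                      cv_folds = 5) {
  if (!k %in% 2:5) abort("k must be one of 2, 3, 4, 5.")
  if (population_size < 4) abort("population_size must be >= 4.")
  for (r in c(crossover_rate, mutation_rate)) {
    if (r < 0 || r > 1) abort("Operator rates must lie in [0, 1].")
  }
  structure(
    list(
      k = as.integer(k), population_size = as.integer(population_size),
      generations = as.integer(generations), crossover_rate = crossover_rate,
      mutation_rate = mutation_rate, elitism_count = as.integer(elitism_count),
      tournament_size = as.integer(tournament_size), seed = as.integer(seed),
      cv_folds = as.integer(cv_folds)
    ),
    class = "ga_config"
  )
}

# Subset-fitness evaluator with per-run memoization: identical subsets map
# to identical fitness within one search.
make_fitness_cache <- function(features, pool, cv_folds, cv_seed) {
  cache <- new.env(parent = emptyenv())
  evals <- 0L
  fitness <- function(idx) {
    idx <- sort(idx)
    key <- paste(idx, collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    rep <- suppressWarnings(suppressMessages(
      cross_validate(features, pool[idx], k = cv_folds, seed = cv_seed)
    ))
    val <- 1 - rep$accuracy / 100
    cache[[key]] <- val
    evals <<- evals + 1L
    val
  }
  list(fitness = fitness, n_evals = function() evals)
}

#' Genetic-algorithm search for the best feature subset of dimension k
#'
#' Generational GA over distinct-index subsets: tournament selection,
#' uniform subset crossover with repair (duplicates removed and refilled
#' from the parents' union, then randomly), per-gene mutation swapping one
#' index for an unused one, and elitist replacement. Fitness is the
#' stratified cross-validated classification error of the subset;
#' evaluations are memoized per subset. Elitism makes the best fitness
#' non-increasing across generations; a fixed seed reproduces the run
#' exactly.
#'
#' @param features Feature tibble from [extract_features()].
#' @param cfg A [ga_config()].
#' @param pool Candidate feature names (default: every extracted feature).
#' @return An object of class `ga_result`: best subset (names + fitness),
#'   per-generation history tibble, and evaluation count.
#' @export
#' @examples
#' rec <- simulate_study(sim_config(duration_s_per_class = 12))
#' feats <- extract_features(epochize(rec))
#' run_ga(feats, ga_config(k = 2, generations = 5, population_size = 10))
run_ga <- function(features, cfg = ga_config(),
                   pool = setdiff(names(features), c("epoch", "label", "start_s"))) {
  check_subset(pool, setdiff(names(features), c("epoch", "label", "start_s")))
  p <- length(pool)
  if (p < cfg$k) abort("Feature pool smaller than subset dimension k.")
  fc <- make_fitness_cache(features, pool, cfg$cv_folds, cfg$seed)

  res <- with_seed(cfg$seed, {
    popn <- replicate(cfg$population_size, sort(sample.int(p, cfg$k)),
                      simplify = FALSE)
    fit <- vapply(popn, fc$fitness, 0)
    history <- numeric(cfg$generations)

    tournament <- function() {
      cand <- sample.int(cfg$population_size, cfg$tournament_size)
      popn[[cand[which.min(fit[cand])]]]
    }
    crossover <- function(p1, p2) {
      if (runif(1) > cfg$crossover_rate) return(p1)
      union_idx <- union(p1, p2)
      take <- union_idx[runif(length(union_idx)) < 0.5]
      if (length(take) > cfg$k) take <- sample(take, cfg$k)
      if (length(take) < cfg$k) {
        refill <- setdiff(union_idx, take)
        extra <- setdiff(seq_len(p), take)
        need <- cfg$k - length(take)
        pickable <- if (length(refill) >= need) refill else extra
        take <- c(take, sample(pickable, need))
      }
      sort(take)
    }
    mutate_chr <- function(ch) {
      for (g in seq_along(ch)) {
        if (runif(1) < cfg$mutation_rate) {
          unused <- setdiff(seq_len(p), ch)
          if (length(unused) > 0) ch[g] <- unused[sample.int(length(unused), 1)]
        }
      }
      sort(ch)
    }

    for (gen in seq_len(cfg$generations)) {
      ord <- order(fit, vapply(popn, function(i) paste(sprintf("%03d", i), collapse = ","), ""))
      elite <- popn[ord[seq_len(min(cfg$elitism_count, cfg$population_size))]]
      offspring <- elite
      while (length(offspring) < cfg$population_size) {
        child <- mutate_chr(crossover(tournament(), tournament()))
        offspring <- c(offspring, list(child))
      }
      popn <- offspring
      fit <- vapply(popn, fc$fitness, 0)
      history[gen] <- min(fit)
    }
    ord <- order(fit, vapply(popn, function(i) paste(sprintf("%03d", i), collapse = ","), ""))
    list(best_idx = popn[[ord[1]]], best_fit = fit[ord[1]], history = history)
  })

  structure(
    list(
      best_features = pool[res$best_idx],
      best_fitness = res$best_fit,
      best_accuracy = 100 * (1 - res$best_fit),
      history = tibble(
        generation = seq_len(cfg$generations),
        best_fitness = res$history
      ),
      n_evaluations = fc$n_evals(),
      config = cfg,
      pool = pool
    ),
    class = "ga_result"
  )
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf(
    "<ga_result> k=%d best {%s}: accuracy %.2f%% (error %.4f), %d fitness evaluations\n",
    x$config$k, paste(x$best_features, collapse = ", "),
    x$best_accuracy, x$best_fitness, x$n_evaluations
  ))
  invisible(x)
}

#' Exhaustive best subset of dimension k (GA oracle)
#'
#' Evaluates every k-subset of the pool with the same cross-validated
#' fitness used by [run_ga()] and returns the minimum-error subset, ties
#' broken lexicographically on sorted feature indices.
#'
#' @param features Feature tibble.
#' @param k Subset dimension.
#' @param pool Candidate feature names.
#' @param cv_folds,cv_seed Cross-validation protocol (must match the GA's
#'   for oracle comparisons).
#' @param max_combinations Refuse pools whose `choose(p, k)` exceeds this.
#' @return List with `features`, `fitness`, `accuracy`, `n_evaluated`.
#' @export
exhaustive_best <- function(features, k,
                            pool = setdiff(names(features), c("epoch", "label", "start_s")),
                            cv_folds = 5, cv_seed = 1L,
                            max_combinations = 20000) {
  p <- length(pool)
  if (p < k) abort("Feature pool smaller than k.")
  n_comb <- choose(p, k)
  if (n_comb > max_combinations) {
    abort(sprintf("choose(%d, %d) = %d exceeds the combinatorial budget %d.",
                  p, k, n_comb, max_combinations))
  }
  fc <- make_fitness_cache(features, pool, cv_folds, cv_seed)
  combos <- combn(p, k)
  fits <- apply(combos, 2, fc$fitness)
  best <- which.min(fits)  # which.min takes the first = lexicographic tie-break
  idx <- combos[, best]
  list(
    features = pool[idx],
    fitness = fits[best],
    accuracy = 100 * (1 - fits[best]),
    n_evaluated = ncol(combos)
  )
}

#' Rank the best feature vectors per dimension
#'
#' For each requested dimension `k`, searches the pool (exhaustively when
#' it fits the combinatorial budget, otherwise by GA) and returns the
#' `top_n` subsets with cross-validated accuracy and per-class
#' sensitivity/specificity, sorted by accuracy descending with a
#' deterministic tie order.
#'
#' @param features Feature tibble.
#' @param ks Dimensions to search, subset of 2:5.
#' @param top_n Subsets reported per dimension.
#' @param pool Candidate feature names.
#' @param cv_folds,seed Evaluation protocol.
#' @param max_combinations Budget above which the GA is used instead of
#'   enumeration.
#' @return Tibble: `k`, `rank`, `features` (slash-joined), `accuracy`, and
#'   a `report` list-column of `classification_report`s.
#' @export
rank_vectors <- function(features, ks = 2:5, top_n = 3,
                         pool = setdiff(names(features), c("epoch", "label", "start_s")),
                         cv_folds = 5, seed = 1L,
                         max_combinations = 20000) {
  if (!all(ks %in% 2:5)) abort("ks must be a subset of 2:5.")
  out <- list()
  for (k in ks) {
    n_comb <- choose(length(pool), k)
    if (n_comb <= max_combinations) {
      fc <- make_fitness_cache(features, pool, cv_folds, seed)
      combos <- combn(length(pool), k)
      fits <- apply(combos, 2, fc$fitness)
      key <- matrix(sprintf("%03d", combos), nrow = nrow(combos))
      ord <- order(fits, apply(key, 2, paste, collapse = ","))
      top <- head(ord, top_n)
      subsets <- lapply(top, function(j) pool[combos[, j]])
    } else {
      ga <- run_ga(features, ga_config(k = k, seed = seed, cv_folds = cv_folds),
                   pool = pool)
      subsets <- list(ga$best_features)
    }
    rows <- purrr::imap(subsets, function(sub, r) {
      rep <- suppressWarnings(suppressMessages(cross_validate(features, sub, k = cv_folds, seed = seed)))
      tibble(
        k = k, rank = r,
        features = paste(sub, collapse = " / "),
        accuracy = rep$accuracy,
        report = list(rep)
      )
    })
    out[[as.character(k)]] <- dplyr::bind_rows(rows)
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$k, .data$rank)
}
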