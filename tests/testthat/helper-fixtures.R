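# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

# Feature matrix of the default synthetic study (60 s/class, fs 128,
# 2 s epochs at 50% overlap, seed 1): 59 epochs per class.
default_study_features <- function() {
  if (is.null(.fixtures$feats)) {
    rec <- simulate_study(sim_config())
    .fixtures$feats <- suppressMessages(extract_features(epochize(rec)))
  }
  .fixtures$feats
}

# A cheaper feature matrix (14 epochs per class) for structural tests.
small_study_features <- function() {
  if (is.null(.fixtures$small)) {
    rec <- simulate_study(sim_config(duration_s_per_class = 15))
    .fixtures$small <- suppressMessages(extract_features(epochize(rec)))
  }
  .fixtures$small
}

# Brute-force ApEn oracle: direct double-loop transcription of the
# definition (self-matches included), independent of the package's
# vectorized implementation.
apen_oracle <- function(x, m = 2, r_frac = 0.2) {
  n <- length(x)
  r <- r_frac * sd(x)
  phi <- function(m) {
    nv <- n - m + 1
    total <- 0
    for (i in seq_len(nv)) {
      cnt <- 0
      for (j in seq_len(nv)) {
        if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) cnt <- cnt + 1
      }
      total <- total + log(cnt / nv)
    }
    total / nv
  }
  phi(m) - phi(m + 1)
}

# Independent LZ76 oracle: production-based parse. Each new phrase is the
# shortest prefix of the remainder that does not occur as a substring of
# everything preceding the phrase's last symbol.
lz76_oracle <- function(bits) {
  s <- paste(bits, collapse = "")
  n <- nchar(s)
  cn <- 0L
  l <- 1L
  while (l <= n) {
    k <- 1L
    while (l + k - 1L <= n) {
      phrase <- substr(s, l, l + k - 1L)
      history <- substr(s, 1L, l + k - 2L)
      if (!grepl(phrase, history, fixed = TRUE)) break
      k <- k + 1L
    }
    if (l + k - 1L > n) k <- n - l + 1L
    cn <- cn + 1L
    l <- l + k
  }
  cn
}

# Synthetic feature table with two jointly (but not singly) separating
# features planted among noise columns; n rows per class.
planted_feature_table <- function(n_per_class = 30, n_noise = 8, seed = 42) {
  states <- anesthesia_states()
  set.seed(seed)
  labs <- rep(states, each = n_per_class)
  n <- length(labs)
  ci <- match(labs, states)
  # f1 splits {AWAKE, LIGHT} vs {DEEP, ISOELECTRIC}; f2 splits within pairs
  f1 <- ifelse(ci <= 2, 0, 4) + rnorm(n, sd = 0.3)
  f2 <- ifelse(ci %% 2 == 1, 0, 4) + rnorm(n, sd = 0.3)
  noise <- matrix(rnorm(n * n_noise), n)
  colnames(noise) <- paste0("N", seq_len(n_noise))
  out <- tibble::as_tibble(noise)
  out$SIG1 <- f1
  out$SIG2 <- f2
  dplyr::bind_cols(
    tibble::tibble(epoch = seq_len(n), label = labs, start_s = 0),
    out
  )
}
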