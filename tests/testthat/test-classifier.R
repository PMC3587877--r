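# Gaussian class-conditional classifier, report metrics, cross-validation.

test_that("well-separated classes are recovered with the boundary between means", {
  tab <- planted_feature_table(n_per_class = 25)
  model <- fit_state_classifier(tab, c("SIG1", "SIG2"))
  pred <- predict(model, tab)
  expect_equal(mean(pred == tab$label), 1)
  expect_identical(fit_state_classifier(tab, c("SIG1", "SIG2")), model)
})

test_that("unknown features and missing classes are rejected informatively", {
  tab <- planted_feature_table()
  expect_error(fit_state_classifier(tab, "NOPE"), "Valid features")
  expect_error(fit_state_classifier(tab, character(0)), "non-empty")
  expect_error(fit_state_classifier(tab[tab$label != "DEEP", ], "SIG1"), "DEEP")
})

test_that("posterior ties break toward the earlier canonical class", {
  set.seed(10)
  n <- 400
  labs <- rep(anesthesia_states(), each = n)
  # symmetric 1-D classes centred at -3, -1, 1, 3
  x <- rep(c(-3, -1, 1, 3), each = n) + rnorm(4 * n, sd = 0.25)
  tab <- tibble::tibble(epoch = seq_along(x), label = labs, start_s = 0, F = x)
  model <- fit_state_classifier(tab, "F")
  # a point midway between LIGHT and DEEP is assigned the earlier class
  mid <- tibble::tibble(F = 0)
  expect_equal(predict(model, mid), "LIGHT")
})

test_that("rows with sentinel values are excluded with a message", {
  tab <- planted_feature_table()
  tab$SIG1[3] <- NA
  expect_message(model <- fit_state_classifier(tab, c("SIG1", "SIG2")),
                 "excluded 1")
  expect_message(pred <- predict(model, tab), "1 row")
  expect_true(is.na(pred[3]))
  expect_message(rep <- evaluate_classification(tab$label, pred), "dropped 1")
  expect_equal(rep$n, nrow(tab) - 1)
})

test_that("report metrics match a hand-computed 4x4 example", {
  states <- anesthesia_states()
  # each true class: 8 correct, 1 to the next class, 1 to the one after
  truth <- rep(states, each = 10)
  pred <- unlist(lapply(1:4, function(i) {
    c(rep(states[i], 8), states[(i %% 4) + 1], states[(i + 1) %% 4 + 1])
  }))
  rep <- evaluate_classification(truth, pred)
  # hand calculation: accuracy 32/40; each class has 8 TP, 2 FN, 2 FP, 28 TN
  expect_equal(rep$accuracy, 80)
  expect_equal(rep$per_class$sensitivity, rep(0.8, 4))
  expect_equal(rep$per_class$specificity, rep(28 / 30, 4))
  expect_equal(rowSums(rep$confusion), setNames(rep(10, 4), states))
})

test_that("degenerate report cases: all correct and fully swapped pairs", {
  states <- anesthesia_states()
  truth <- rep(states, each = 5)
  perfect <- evaluate_classification(truth, truth)
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$per_class$sensitivity, rep(1, 4))
  expect_equal(perfect$per_class$specificity, rep(1, 4))

  t2 <- rep(c("AWAKE", "LIGHT"), each = 10)
  p2 <- rep(c("LIGHT", "AWAKE"), each = 10)
  swapped <- evaluate_classification(t2, p2)
  expect_equal(swapped$accuracy, 0)
  expect_equal(swapped$per_class$specificity[1:2], c(0, 0))
  expect_error(evaluate_classification(character(0), character(0)), "Empty")
  expect_error(evaluate_classification(t2, p2[1:5]), "equal length")
})

test_that("accuracy is invariant under feature-column permutation", {
  feats <- default_study_features()
  sub <- c("AE", "SE", "BS%")
  r1 <- suppressWarnings(cross_validate(feats, sub, seed = 1))
  r2 <- suppressWarnings(cross_validate(feats, rev(sub), seed = 1))
  expect_equal(r1$accuracy, r2$accuracy)
  expect_equal(r1$confusion, r2$confusion)
})

test_that("stratified cross-validation is reproducible under its seed", {
  feats <- small_study_features()
  r1 <- cross_validate(feats, c("AE", "SE"), seed = 42)
  r2 <- cross_validate(feats, c("AE", "SE"), seed = 42)
  expect_identical(r1, r2)
})

test_that("singular covariance triggers the ridge warning but still predicts", {
  tab <- planted_feature_table()
  tab$CONST <- 5  # zero variance everywhere
  w <- capture_warnings(model <- fit_state_classifier(tab, c("SIG1", "SIG2", "CONST")))
  expect_true(all(grepl("ridge", w)))
  expect_gte(length(w), 1)
  pred <- predict(model, tab)
  expect_equal(mean(pred == tab$label), 1)
})

test_that("the quadratic rule agrees with an independent QDA implementation", {
  skip_if_not_installed("MASS")
  feats <- default_study_features()
  sub <- c("AE", "SE", "L-Z V")
  X <- scale(as.matrix(feats[, sub]))
  colnames(X) <- c("a", "b", "c")
  ref <- MASS::qda(x = as.data.frame(X), grouping = factor(feats$label))
  ref_pred <- as.character(predict(ref, as.data.frame(X))$class)
  model <- fit_state_classifier(feats, sub)
  own_pred <- predict(model, feats)
  expect_gt(mean(own_pred == ref_pred), 0.99)
})

test_that("the entropy quadruple dominates each of its single members", {
  feats <- default_study_features()
  quad <- c("AE", "L-Z V", "RE(3)", "SE")
  acc_quad <- suppressWarnings(cross_validate(feats, quad, seed = 1))$accuracy
  for (f in quad) {
    expect_gte(acc_quad, suppressWarnings(cross_validate(feats, f, seed = 1))$accuracy)
  }
})
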