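test_that("feature-set enumeration", {
  sets <- enumerate_feature_sets()
  expect_length(sets, 120)  # C(15,1) + C(15,2)
  expect_length(enumerate_feature_sets(c("a", "b")), 3)
  expect_length(enumerate_feature_sets("a", max_size = 1), 1)
  expect_error(enumerate_feature_sets(c("a", "a")), "duplicate")
  sizes <- lengths(sets)
  expect_equal(sum(sizes == 1), 15)
  expect_equal(sum(sizes == 2), 105)
})

test_that("LOSO partitions are singleton, disjoint and exhaustive", {
  for (n in c(2, 7, 30)) {
    f <- loso_folds(n)
    expect_length(f, n)
    tests <- vapply(f, function(x) x$test, 0L)
    expect_equal(sort(tests), seq_len(n))
    for (i in seq_len(n)) {
      expect_length(f[[i]]$test, 1)
      expect_equal(sort(c(f[[i]]$train, f[[i]]$test)), seq_len(n))
    }
  }
  expect_error(loso_folds(1), "at least 2")
})

test_that("evaluation accuracy accounting and determinism", {
  b <- make_blob_features(seed = 5, gap = 1.2)
  ev <- evaluate_model(b$features, b$labels, classifier_spec("KNN"),
                       feature_names = c("mean_step_length_m",
                                         "speed_to_get_up_mps"), seed = 1)
  expect_equal(ev$n_used, 30)
  expect_length(ev$per_fold_correct, 30)
  # mean accuracy times n is an integer count of correct folds
  expect_equal(ev$mean_accuracy * ev$n_used, sum(ev$per_fold_correct))
  ev2 <- evaluate_model(b$features, b$labels, classifier_spec("KNN"),
                        feature_names = c("mean_step_length_m",
                                          "speed_to_get_up_mps"), seed = 1)
  expect_identical(ev[c("per_fold_correct", "mean_accuracy")],
                   ev2[c("per_fold_correct", "mean_accuracy")])
})

test_that("perfectly separable features reach accuracy 1 with KNN", {
  b <- make_blob_features(seed = 9, gap = 4)
  ev <- evaluate_model(b$features, b$labels, classifier_spec("KNN"),
                       feature_names = c("mean_step_length_m",
                                         "speed_to_get_up_mps"))
  expect_equal(ev$mean_accuracy, 1)
})

test_that("shuffled labels drop accuracy toward the majority baseline", {
  b <- make_blob_features(seed = 13, gap = 4)
  set.seed(4)
  shuffled <- sample(b$labels)
  accs <- vapply(1:5, function(s) {
    set.seed(s)
    evaluate_model(b$features, sample(b$labels), classifier_spec("KNN"),
                   feature_names = c("mean_step_length_m",
                                     "speed_to_get_up_mps"),
                   seed = s)$mean_accuracy
  }, 0)
  expect_lt(mean(accs), 0.9)   # far below the separable 1.0
  expect_gt(mean(accs), 0.3)   # but not degenerate
})

test_that("subjects with missing features are dropped and logged", {
  b <- make_blob_features(seed = 2)
  b$features$mean_step_length_m[4] <- NA
  ev <- evaluate_model(b$features, b$labels, classifier_spec("NB"),
                       feature_names = c("mean_step_length_m",
                                         "speed_to_get_up_mps"))
  expect_equal(ev$n_used, 29)
  expect_equal(ev$dropped_subjects, b$features$subject_id[4])
})

test_that("standardization is training-fold only (no-leakage audit)", {
  b <- make_blob_features(seed = 6)
  ev <- evaluate_model(b$features, b$labels, classifier_spec("NB"),
                       feature_names = c("mean_step_length_m",
                                         "speed_to_get_up_mps"))
  expect_true(audit_no_leakage(ev, b$features, b$labels))
  # tampering with a stored scaler (as full-data stats would) must fail
  ev_bad <- ev
  full <- fallwatch:::fit_scaler(as.matrix(b$features[, -1]))
  ev_bad$fold_scalers[[1]] <- full
  expect_error(audit_no_leakage(ev_bad, b$features, b$labels), "leakage")
})

test_that("separable cohorts admit a perfect two-parameter combination", {
  for (seed in 1:3) {
    pm <- sample_parameter_matrix(cohort_config(separation_mode = "separable",
                                                day_duration = 600), seed)
    labels <- ifelse(pm$group == "low", "low", "high")
    best <- max(vapply(c("KNN", "NB", "NN"), function(alg)
      evaluate_model(pm, labels, classifier_spec(alg, seed = seed),
                     feature_names = c("mean_step_length_m",
                                       "speed_to_get_up_mps"),
                     seed = seed)$mean_accuracy, 0))
    expect_equal(best, 1)
  }
})

test_that("ranked leaderboard groups ties and sorts by accuracy", {
  b <- make_blob_features(seed = 3, gap = 4)
  bench <- benchmark_combinations(
    b$features, b$labels, algorithms = c("KNN", "NB"),
    parameters = c("mean_step_length_m", "speed_to_get_up_mps"))
  lb <- bench$leaderboard
  expect_equal(nrow(lb), 3)  # 2 singletons + 1 pair
  expect_true(all(diff(lb$mean_accuracy) <= 0))
  top <- lb[1, ]
  expect_gte(top$mean_accuracy, max(lb$mean_accuracy))
  # single result ranks as itself
  single <- rank_results(bench$results[1])
  expect_equal(nrow(single), 1)
})

test_that("decision grid agrees with the model and covers both classes", {
  b <- make_blob_features(seed = 8, gap = 3)
  grid <- fit_decision_grid(b$features, b$labels,
                            c("mean_step_length_m", "speed_to_get_up_mps"),
                            classifier_spec("KNN"), resolution = 40)
  expect_setequal(unique(grid$class), c("low", "high"))
  # grid predictions at training points equal direct model predictions
  model <- attr(grid, "model"); sc <- attr(grid, "scaler")
  Xs <- fallwatch:::apply_scaler(sc, as.matrix(b$features[, -1]))
  expect_equal(predict(model, Xs), b$labels)
  expect_error(decision_grid(model, sc,
                             bounds = list(xlim = c(1, 1), ylim = c(0, 1))),
               "degenerate")
})

test_that("two-point KNN grid splits along the perpendicular bisector", {
  f <- data.frame(subject_id = c("A", "B"),
                  mean_step_length_m = c(0, 1),
                  speed_to_get_up_mps = c(0, 1))
  m <- train_classifier(as.matrix(f[, -1]), c("a", "b"), classifier_spec("KNN"))
  g <- decision_grid(m, NULL, bounds = list(xlim = c(-1, 2), ylim = c(-1, 2)),
                     resolution = 21)
  d_a <- sqrt(g$x^2 + g$y^2)
  d_b <- sqrt((g$x - 1)^2 + (g$y - 1)^2)
  off_bisector <- abs(d_a - d_b) > 1e-9
  expect_equal(g$class[off_bisector],
               ifelse(d_a[off_bisector] < d_b[off_bisector], "a", "b"))
})
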