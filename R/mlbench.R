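#' Enumerate 1- and 2-parameter feature combinations
#'
#' All C(n,1) + C(n,2) combinations of the parameter names, in lexicographic
#' order over the supplied name order (singletons first).
#'
#' @param names Character vector of unique parameter names (default the 15
#'   canonical parameters).
#' @param max_size Largest combination size (default 2).
#' @return List of character vectors.
#' @export
enumerate_feature_sets <- function(names = parameter_names(), max_size = 2) {
  if (anyDuplicated(names)) stopf("duplicate parameter names")
  out <- list()
  for (size in seq_len(max_size)) {
    cmb <- utils::combn(names, size, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

#' Leave-one-subject-out partitions
#'
#' @param n_subjects Cohort size (>= 2).
#' @return List of `n_subjects` folds; fold `i` is
#'   `list(test = i, train = setdiff(1:n, i))`.
#' @export
loso_folds <- function(n_subjects) {
  if (n_subjects < 2) stopf("need at least 2 subjects for LOSO")
  lapply(seq_len(n_subjects), function(i)
    list(test = i, train = setdiff(seq_len(n_subjects), i)))
}

# z-score standardization fitted on training rows only; zero-sd columns are
# passed through unscaled (sd treated as 1)
fit_scaler <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(center = mu, scale = sd)
}
apply_scaler <- function(scaler, X)
  sweep(sweep(X, 2, scaler$center), 2, scaler$scale, "/")

#' Evaluate one feature combination with one classifier under LOSO
#'
#' Per fold, features are standardized on the training rows only (mean 0,
#' sd 1), the classifier is fitted on the training subjects and the held-out
#' subject is predicted. Mean accuracy is the number of correct predictions
#' over the number of predictions (with singleton test folds this equals the
#' mean over folds). Subjects with a missing value in any requested feature
#' are dropped from the evaluation of that combination and recorded.
#'
#' @param features data.frame with `subject_id` and parameter columns.
#' @param labels Character/factor vector of class labels aligned with
#'   `features` rows (never used as a predictor).
#' @param spec A [classifier_spec()].
#' @param feature_names Columns to use (1 or 2 names); defaults to all
#'   parameter columns present.
#' @param folds Optional partition list from [loso_folds()].
#' @param seed Seed for stochastic learners; per-fold seeds are derived
#'   deterministically.
#' @return Object of class `fw_eval`: list with `feature_names`, `algorithm`,
#'   `per_fold_correct`, `predictions`, `mean_accuracy`, `n_used`,
#'   `dropped_subjects`, and the per-fold scaler statistics (`fold_scalers`)
#'   retained for the no-leakage audit.
#' @export
evaluate_model <- function(features, labels, spec, feature_names = NULL,
                           folds = NULL, seed = 0) {
  feature_names <- feature_names %||%
    intersect(parameter_names(), names(features))
  miss <- setdiff(feature_names, names(features))
  if (length(miss)) stopf("unknown feature(s): %s", paste(miss, collapse = ", "))
  X_all <- as.matrix(features[, feature_names, drop = FALSE])
  labels <- as.character(labels)
  keep <- stats::complete.cases(X_all) & !is.na(labels)
  dropped <- if ("subject_id" %in% names(features))
    features$subject_id[!keep] else which(!keep)
  X <- X_all[keep, , drop = FALSE]
  y <- labels[keep]
  n <- nrow(X)
  folds <- folds %||% loso_folds(n)
  correct <- logical(length(folds))
  preds <- character(length(folds))
  scalers <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    tr <- folds[[f]]$train; te <- folds[[f]]$test
    sc <- fit_scaler(X[tr, , drop = FALSE])
    scalers[[f]] <- sc
    model <- train_classifier(apply_scaler(sc, X[tr, , drop = FALSE]),
                              y[tr], spec, seed = derive_seed(seed, f))
    p <- predict(model, apply_scaler(sc, X[te, , drop = FALSE]))
    preds[f] <- p[1]
    correct[f] <- all(p == y[te])
  }
  ids <- if ("subject_id" %in% names(features))
    features$subject_id[keep] else as.character(seq_len(n))
  structure(list(
    feature_names = feature_names, algorithm = spec$algorithm,
    per_fold_correct = stats::setNames(correct,
      vapply(folds, function(f) ids[f$test[1]], "")),
    predictions = preds,
    mean_accuracy = mean(correct), n_used = n,
    dropped_subjects = dropped, fold_scalers = scalers
  ), class = "fw_eval")
}

#' Audit an evaluation for standardization leakage
#'
#' Recomputes every fold's training-only standardization statistics from the
#' raw features and fails if the statistics stored during evaluation differ
#' (i.e., if any test row contaminated them) or if a fold's test subject
#' appears in its training set.
#'
#' @param result An `fw_eval`.
#' @param features,labels The inputs given to [evaluate_model()].
#' @param folds The partition list used (defaults to LOSO on the used rows).
#' @return TRUE invisibly; error on contamination.
#' @export
audit_no_leakage <- function(result, features, labels, folds = NULL) {
  X_all <- as.matrix(features[, result$feature_names, drop = FALSE])
  keep <- stats::complete.cases(X_all) & !is.na(as.character(labels))
  X <- X_all[keep, , drop = FALSE]
  folds <- folds %||% loso_folds(nrow(X))
  for (f in seq_along(folds)) {
    if (length(intersect(folds[[f]]$train, folds[[f]]$test)))
      stopf("leakage: fold %d test subject in training set", f)
    ref <- fit_scaler(X[folds[[f]]$train, , drop = FALSE])
    got <- result$fold_scalers[[f]]
    if (max(abs(ref$center - got$center), abs(ref$scale - got$scale)) > 1e-12)
      stopf("leakage: fold %d scaler was not computed on training rows only", f)
  }
  invisible(TRUE)
}

#' Benchmark all feature combinations across classifiers
#'
#' Evaluates every 1- and 2-parameter combination with every requested
#' classifier under leave-one-subject-out cross-validation.
#'
#' @param features data.frame with `subject_id` + parameter columns.
#' @param labels Aligned class labels.
#' @param algorithms Character vector of algorithms (default all nine).
#' @param max_size Largest combination size (default 2).
#' @param seed Master seed for stochastic learners.
#' @param parameters Parameter names to combine (default all 15 present).
#' @return List of class `fw_benchmark`: `results` (list of `fw_eval`) and
#'   `leaderboard` (see [rank_results()]).
#' @export
benchmark_combinations <- function(features, labels,
                                   algorithms = FW_ALGORITHMS,
                                   max_size = 2, seed = 0,
                                   parameters = NULL) {
  parameters <- parameters %||% intersect(parameter_names(), names(features))
  combos <- enumerate_feature_sets(parameters, max_size)
  results <- vector("list", length(combos) * length(algorithms))
  k <- 0
  for (cmb in combos) {
    for (alg in algorithms) {
      k <- k + 1
      results[[k]] <- evaluate_model(
        features, labels, classifier_spec(alg, seed = seed),
        feature_names = cmb, seed = derive_seed(seed, k))
    }
  }
  structure(list(results = results, leaderboard = rank_results(results)),
            class = "fw_benchmark")
}

#' Rank evaluation results into a leaderboard
#'
#' Sorts combinations by best mean accuracy (descending); for each
#' combination, all algorithms attaining its best score are listed together.
#'
#' @param results List of `fw_eval` objects.
#' @return data.frame: `features`, `algorithms`, `mean_accuracy`,
#'   `n_parameters`.
#' @export
rank_results <- function(results) {
  if (!length(results)) stopf("no results to rank")
  key <- vapply(results, function(r) paste(r$feature_names, collapse = " + "), "")
  acc <- vapply(results, `[[`, 0, "mean_accuracy")
  alg <- vapply(results, `[[`, "", "algorithm")
  rows <- lapply(unique(key), function(k) {
    i <- which(key == k)
    best <- max(acc[i])
    data.frame(features = k,
               algorithms = paste(alg[i][acc[i] == best], collapse = ", "),
               mean_accuracy = best,
               n_parameters = length(results[[i[1]]]$feature_names),
               stringsAsFactors = FALSE)
  })
  lb <- do.call(rbind, rows)
  lb[order(-lb$mean_accuracy, lb$n_parameters, lb$features), , drop = FALSE]
}

#' Decision grid for a trained two-feature model
#'
#' Evaluates a trained classifier on a regular grid spanning the requested
#' bounds, for decision-boundary maps of a feature pair. Inputs are given on
#' the original feature scale; the scaler used at training time is applied.
#'
#' @param model An `fw_model` trained on exactly two features.
#' @param scaler The training scaler (`list(center, scale)`) or NULL for
#'   identity.
#' @param bounds List/matrix with `xlim` and `ylim` (each `c(lo, hi)`).
#' @param resolution Grid nodes per axis (default 100).
#' @return data.frame `x, y, class` of class `fw_decision_grid`, with the
#'   bounds and feature names as attributes.
#' @export
decision_grid <- function(model, scaler = NULL, bounds, resolution = 100) {
  xl <- bounds$xlim; yl <- bounds$ylim
  if (diff(xl) <= 0 || diff(yl) <= 0) stopf("degenerate grid bounds")
  gx <- seq(xl[1], xl[2], length.out = resolution)
  gy <- seq(yl[1], yl[2], length.out = resolution)
  G <- as.matrix(expand.grid(x = gx, y = gy))
  Gs <- if (is.null(scaler)) G else apply_scaler(scaler, G)
  cls <- predict(model, Gs)
  structure(data.frame(x = G[, 1], y = G[, 2], class = cls,
                       stringsAsFactors = FALSE),
            bounds = bounds, class = c("fw_decision_grid", "data.frame"))
}

#' Train on a feature pair and compute its decision grid
#'
#' Convenience wrapper: standardizes the full feature pair, trains the
#' classifier, and grids the observed range plus a margin.
#'
#' @param features,labels As in [evaluate_model()].
#' @param feature_pair Two parameter names.
#' @param spec A [classifier_spec()].
#' @param margin Fractional range margin added around the data (default 0.15).
#' @param resolution Grid nodes per axis.
#' @param seed Seed for stochastic learners.
#' @return A `fw_decision_grid` (the trained model attached as attribute
#'   `"model"`).
#' @export
fit_decision_grid <- function(features, labels, feature_pair, spec,
                              margin = 0.15, resolution = 100, seed = 0) {
  X <- as.matrix(features[, feature_pair, drop = FALSE])
  keep <- stats::complete.cases(X) & !is.na(as.character(labels))
  X <- X[keep, , drop = FALSE]
  sc <- fit_scaler(X)
  model <- train_classifier(apply_scaler(sc, X), as.character(labels)[keep],
                            spec, seed = seed)
  rng <- apply(X, 2, range)
  pad <- margin * (rng[2, ] - rng[1, ])
  grid <- decision_grid(model, sc,
                        bounds = list(xlim = c(rng[1, 1] - pad[1], rng[2, 1] + pad[1]),
                                      ylim = c(rng[1, 2] - pad[2], rng[2, 2] + pad[2])),
                        resolution = resolution)
  attr(grid, "model") <- model
  attr(grid, "scaler") <- sc
  grid
}
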