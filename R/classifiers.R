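# Nine reference classifiers with fixed hyperparameters. No fitting library
# for trees, boosting, MLPs or SVMs is assumed; everything below is
# self-contained (the SVM dual uses quadprog). Classes are handled as a
# 2-level factor; "class index" in tie-breaks refers to the level order.

FW_ALGORITHMS <- c("DT", "AB", "NN", "NB", "KNN", "SVM_linear", "SVM_rbf",
                   "RF", "QDA")

#' Classifier specification
#'
#' Fixed hyperparameter set per algorithm: decision tree (max depth 5),
#' AdaBoost (50 depth-1 stumps), neural net (one hidden layer of 100 units,
#' 500 full-batch Adam iterations), Gaussian naive Bayes (priors from data),
#' k-nearest neighbors (k = 3), linear SVM (C = 0.025), RBF SVM (C = 1,
#' gamma = 1/(d * var)), random forest (10 trees, max depth 5) and QDA
#' (priors from data).
#'
#' @param algorithm One of `"DT","AB","NN","NB","KNN","SVM_linear","SVM_rbf",
#'   "RF","QDA"`.
#' @param seed Seed for stochastic learners (NN, RF); deterministic learners
#'   ignore it.
#' @return List of class `fw_classifier_spec`.
#' @export
classifier_spec <- function(algorithm, seed = NULL) {
  algorithm <- match.arg(algorithm, FW_ALGORITHMS)
  hp <- switch(algorithm,
    DT = list(max_depth = 5),
    AB = list(n_estimators = 50, base_depth = 1),
    NN = list(hidden = 100, iterations = 500, learning_rate = 1e-3),
    NB = list(var_smoothing = 1e-9),
    KNN = list(k = 3),
    SVM_linear = list(C = 0.025, kernel = "linear"),
    SVM_rbf = list(C = 1, kernel = "rbf"),
    RF = list(n_trees = 10, max_depth = 5),
    QDA = list(reg = 1e-8)
  )
  structure(list(algorithm = algorithm, hyperparameters = hp, seed = seed),
            class = "fw_classifier_spec")
}

## ---- decision tree (CART, Gini) ------------------------------------------

gini_weighted <- function(w_pos, w_tot) {
  if (w_tot <= 0) return(0)
  p <- w_pos / w_tot
  2 * p * (1 - p)
}

# exhaustive best split on X (matrix), binary y (0/1), weights w.
# Ties broken toward the first feature, then the lowest threshold.
best_split <- function(X, y, w, features) {
  n <- length(y)
  parent <- gini_weighted(sum(w[y == 1]), sum(w))
  best <- NULL
  for (j in features) {
    o <- order(X[, j], method = "radix")
    xs <- X[o, j]; ys <- y[o]; ws <- w[o]
    distinct <- which(diff(xs) > 0)
    if (!length(distinct)) next
    cw <- cumsum(ws); cwp <- cumsum(ws * ys)
    W <- cw[n]; WP <- cwp[n]
    for (i in distinct) {
      gl <- gini_weighted(cwp[i], cw[i])
      gr <- gini_weighted(WP - cwp[i], W - cw[i])
      imp <- (cw[i] * gl + (W - cw[i]) * gr) / W
      gain <- parent - imp
      thr <- (xs[i] + xs[i + 1]) / 2
      if (gain > 1e-12 &&
          (is.null(best) || gain > best$gain + 1e-12)) {
        best <- list(feature = j, threshold = thr, gain = gain)
      }
    }
  }
  best
}

build_tree <- function(X, y, w, depth, max_depth, mtry = NULL) {
  wp <- sum(w[y == 1]); wn <- sum(w) - wp
  leaf <- list(leaf = TRUE, class = if (wp > wn) 1L else 0L,
               prob = wp / max(wp + wn, 1e-300))
  if (depth >= max_depth || length(y) < 2 || wp == 0 || wn == 0) return(leaf)
  features <- if (is.null(mtry)) seq_len(ncol(X)) else
    sort(sample.int(ncol(X), mtry))
  sp <- best_split(X, y, w, features)
  if (is.null(sp)) return(leaf)
  left <- X[, sp$feature] <= sp$threshold
  if (!any(left) || all(left)) return(leaf)
  list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
       left = build_tree(X[left, , drop = FALSE], y[left], w[left],
                         depth + 1, max_depth, mtry),
       right = build_tree(X[!left, , drop = FALSE], y[!left], w[!left],
                          depth + 1, max_depth, mtry))
}

predict_tree <- function(tree, X) {
  out <- integer(nrow(X))
  rec <- function(node, idx) {
    if (!length(idx)) return()
    if (node$leaf) { out[idx] <<- node$class; return() }
    left <- X[idx, node$feature] <= node$threshold
    rec(node$left, idx[left]); rec(node$right, idx[!left])
  }
  rec(tree, seq_len(nrow(X)))
  out
}

tree_depth <- function(node) {
  if (node$leaf) return(0L)
  1L + max(tree_depth(node$left), tree_depth(node$right))
}

## ---- individual fitters ---------------------------------------------------

fit_dt <- function(X, y01, hp) {
  list(tree = build_tree(X, y01, rep(1 / length(y01), length(y01)),
                         0, hp$max_depth))
}

fit_ab <- function(X, y01, hp) {
  n <- length(y01)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  for (m in seq_len(hp$n_estimators)) {
    tr <- build_tree(X, y01, w, 0, hp$base_depth)
    pred <- predict_tree(tr, X)
    mis <- pred != y01
    err <- sum(w[mis])
    if (err <= 1e-12) {
      stumps[[length(stumps) + 1]] <- tr
      alphas <- c(alphas, 20)  # effectively infinite vote
      break
    }
    if (err >= 0.5) break
    a <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1]] <- tr
    alphas <- c(alphas, a)
    w <- w * exp(ifelse(mis, a, -a))
    w <- w / sum(w)
  }
  if (!length(stumps)) { # degenerate: fall back to a single majority stump
    stumps <- list(build_tree(X, y01, rep(1 / n, n), 0, 0))
    alphas <- 1
  }
  list(stumps = stumps, alphas = alphas)
}

predict_ab <- function(model, X) {
  score <- rep(0, nrow(X))
  for (m in seq_along(model$stumps)) {
    p <- predict_tree(model$stumps[[m]], X)
    score <- score + model$alphas[m] * ifelse(p == 1, 1, -1)
  }
  as.integer(score > 0)
}

fit_nn <- function(X, y01, hp, seed) {
  d <- ncol(X); h <- hp$hidden
  with_seed(seed %||% 0, {
    lim1 <- sqrt(6 / (d + h)); lim2 <- sqrt(6 / (h + 1))
    W1 <- matrix(stats::runif(d * h, -lim1, lim1), d, h)
    b1 <- rep(0, h)
    W2 <- matrix(stats::runif(h, -lim2, lim2), h, 1)
    b2 <- 0
    mW1 <- vW1 <- matrix(0, d, h); mb1 <- vb1 <- rep(0, h)
    mW2 <- vW2 <- matrix(0, h, 1); mb2 <- vb2 <- 0
    lr <- hp$learning_rate; b1m <- 0.9; b2m <- 0.999; eps <- 1e-8
    n <- nrow(X); yv <- matrix(y01, n, 1)
    for (it in seq_len(hp$iterations)) {
      A1 <- X %*% W1 + matrix(b1, n, h, byrow = TRUE)
      H <- pmax(A1, 0)
      Z <- H %*% W2 + b2
      P <- 1 / (1 + exp(-Z))
      dZ <- (P - yv) / n
      gW2 <- t(H) %*% dZ; gb2 <- sum(dZ)
      dH <- dZ %*% t(W2) * (A1 > 0)
      gW1 <- t(X) %*% dH; gb1 <- colSums(dH)
      upd <- function(m, v, g) {
        m <- b1m * m + (1 - b1m) * g
        v <- b2m * v + (1 - b2m) * g^2
        mh <- m / (1 - b1m^it); vh <- v / (1 - b2m^it)
        list(m = m, v = v, step = lr * mh / (sqrt(vh) + eps))
      }
      u <- upd(mW1, vW1, gW1); mW1 <- u$m; vW1 <- u$v; W1 <- W1 - u$step
      u <- upd(mb1, vb1, gb1); mb1 <- u$m; vb1 <- u$v; b1 <- b1 - u$step
      u <- upd(mW2, vW2, gW2); mW2 <- u$m; vW2 <- u$v; W2 <- W2 - u$step
      u <- upd(mb2, vb2, gb2); mb2 <- u$m; vb2 <- u$v; b2 <- b2 - u$step
    }
    list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  })
}

predict_nn <- function(model, X) {
  n <- nrow(X)
  H <- pmax(X %*% model$W1 + matrix(model$b1, n, length(model$b1),
                                    byrow = TRUE), 0)
  Z <- H %*% model$W2 + model$b2
  as.integer(Z > 0)
}

fit_nb <- function(X, y01, hp) {
  eps <- hp$var_smoothing * max(apply(X, 2, stats::var), 1e-12)
  stats_for <- function(cls) {
    Xi <- X[y01 == cls, , drop = FALSE]
    v <- apply(Xi, 2, function(col)   # ML (population) variance, sklearn-style
      if (length(col) < 2) 0 else stats::var(col) * (length(col) - 1) / length(col))
    list(mean = colMeans(Xi), var = v + eps, prior = nrow(Xi) / nrow(X))
  }
  list(c0 = stats_for(0), c1 = stats_for(1))
}

predict_nb <- function(model, X) {
  ll <- function(s) {
    v <- pmax(s$var, 1e-12)
    rowSums(-0.5 * log(2 * pi * matrix(v, nrow(X), ncol(X), byrow = TRUE)) -
            0.5 * sweep(X, 2, s$mean)^2 /
              matrix(v, nrow(X), ncol(X), byrow = TRUE)) + log(max(s$prior, 1e-300))
  }
  as.integer(ll(model$c1) > ll(model$c0))
}

fit_knn <- function(X, y01, hp) list(X = X, y = y01, k = hp$k)

predict_knn <- function(model, X) {
  n <- nrow(X)
  out <- integer(n)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(model$X) - X[i, ])^2))
    o <- order(d, seq_along(d))       # distance, then training index
    nb <- o[seq_len(min(model$k, length(o)))]
    votes <- tabulate(model$y[nb] + 1L, 2L)
    out[i] <- if (votes[2] > votes[1]) 1L
      else if (votes[1] > votes[2]) 0L
      else model$y[nb[1]]             # tie: nearest neighbor, then class 0
  }
  out
}

# Soft-margin SVM via the dual QP (quadprog). Deterministic.
fit_svm <- function(X, y01, hp) {
  y <- ifelse(y01 == 1, 1, -1)
  n <- nrow(X)
  gamma <- if (hp$kernel == "rbf") 1 / (ncol(X) * max(stats::var(as.vector(X)), 1e-12))
    else NA_real_
  K <- if (hp$kernel == "linear") X %*% t(X) else {
    d2 <- as.matrix(stats::dist(X))^2
    exp(-gamma * d2)
  }
  Dmat <- (y %*% t(y)) * K + diag(1e-8, n)
  dvec <- rep(1, n)
  Amat <- cbind(y, diag(n), -diag(n))
  bvec <- c(0, rep(0, n), rep(-hp$C, n))
  sol <- quadprog::solve.QP(Dmat, dvec, Amat, bvec, meq = 1)
  a <- pmin(pmax(sol$solution, 0), hp$C)
  sv <- a > 1e-8
  f_no_b <- as.vector(K %*% (a * y))
  margin <- sv & a < hp$C - 1e-8
  b <- if (any(margin)) mean(y[margin] - f_no_b[margin]) else {
    up <- f_no_b[(y == -1 & a < hp$C - 1e-8) | (y == 1 & a > 1e-8)]
    lo <- f_no_b[(y == 1 & a < hp$C - 1e-8) | (y == -1 & a > 1e-8)]
    -(max(lo, -Inf) + min(up, Inf)) / 2
  }
  if (!is.finite(b)) b <- -mean(f_no_b)
  list(X = X, ay = a * y, b = b, kernel = hp$kernel, gamma = gamma)
}

predict_svm <- function(model, X) {
  K <- if (model$kernel == "linear") X %*% t(model$X) else {
    d2 <- outer(rowSums(X^2), rowSums(model$X^2), "+") -
      2 * X %*% t(model$X)
    exp(-model$gamma * pmax(d2, 0))
  }
  f <- as.vector(K %*% model$ay) + model$b
  as.integer(f > 0)
}

fit_rf <- function(X, y01, hp, seed) {
  with_seed(seed %||% 0, {
    mtry <- max(1L, floor(sqrt(ncol(X))))
    lapply(seq_len(hp$n_trees), function(t) {
      idx <- sample.int(length(y01), replace = TRUE)
      build_tree(X[idx, , drop = FALSE], y01[idx],
                 rep(1 / length(idx), length(idx)),
                 0, hp$max_depth, mtry = mtry)
    })
  })
}

predict_rf <- function(model, X) {
  votes <- rowSums(vapply(model, function(tr) predict_tree(tr, X),
                          integer(nrow(X))))
  as.integer(votes > length(model) / 2)
}

fit_qda <- function(X, y01, hp) {
  fit1 <- function(cls) {
    Xi <- X[y01 == cls, , drop = FALSE]
    S <- stats::cov(Xi)
    S <- S + diag(hp$reg * max(mean(diag(S)), 1e-8), ncol(X))
    list(mean = colMeans(Xi), Sinv = solve(S),
         logdet = determinant(S, logarithm = TRUE)$modulus[1],
         prior = nrow(Xi) / nrow(X))
  }
  list(c0 = fit1(0), c1 = fit1(1))
}

predict_qda <- function(model, X) {
  disc <- function(s) {
    D <- sweep(X, 2, s$mean)
    -0.5 * rowSums((D %*% s$Sinv) * D) - 0.5 * s$logdet +
      log(max(s$prior, 1e-300))
  }
  as.integer(disc(model$c1) > disc(model$c0))
}

## ---- public train/predict -------------------------------------------------

#' Train a classifier
#'
#' @param X Numeric matrix (or data.frame) of predictors (already
#'   standardized by the caller when scale matters).
#' @param y Two-level factor or character vector of class labels.
#' @param spec A [classifier_spec()].
#' @param seed Optional override for the spec's seed (stochastic learners).
#' @return Object of class `fw_model`.
#' @export
train_classifier <- function(X, y, spec, seed = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  levels <- if (is.factor(y)) levels(y) else sort(unique(as.character(y)))
  if (length(levels) != 2) stopf("labels must be binary; got %d classes",
                                 length(levels))
  y01 <- as.integer(as.character(y) == levels[2])
  seed <- seed %||% spec$seed
  hp <- spec$hyperparameters
  fit <- switch(spec$algorithm,
    DT = fit_dt(X, y01, hp),
    AB = fit_ab(X, y01, hp),
    NN = fit_nn(X, y01, hp, seed),
    NB = fit_nb(X, y01, hp),
    KNN = fit_knn(X, y01, hp),
    SVM_linear = fit_svm(X, y01, hp),
    SVM_rbf = fit_svm(X, y01, hp),
    RF = fit_rf(X, y01, hp, seed),
    QDA = fit_qda(X, y01, hp)
  )
  structure(list(spec = spec, fit = fit, levels = levels,
                 n_features = ncol(X)), class = "fw_model")
}

#' Predict with a trained classifier
#'
#' @param object An `fw_model` from [train_classifier()].
#' @param newdata Numeric matrix/data.frame with the training columns.
#' @param ... Unused.
#' @return Character vector of predicted class labels.
#' @export
predict.fw_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  storage.mode(X) <- "double"
  p01 <- switch(object$spec$algorithm,
    DT = predict_tree(object$fit$tree, X),
    AB = predict_ab(object$fit, X),
    NN = predict_nn(object$fit, X),
    NB = predict_nb(object$fit, X),
    KNN = predict_knn(object$fit, X),
    SVM_linear = predict_svm(object$fit, X),
    SVM_rbf = predict_svm(object$fit, X),
    RF = predict_rf(object$fit, X),
    QDA = predict_qda(object$fit, X)
  )
  object$levels[p01 + 1L]
}
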