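# Independent oracles used across the suite. Deliberately naive O(n^2)
# implementations, kept separate from the package's code paths.

# Brute-force Holm step-down: sort, multiply by (m - rank + 1), enforce
# monotonicity, cap at 1, return in input order.
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  raw <- (m - seq_len(m) + 1) * p[o]
  adj <- pmin(cummax(raw), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Brute-force local maxima with prominence: for each strict local max, walk
# out to the nearest higher sample on each side (or the edge), take the
# minimum en route; prominence = peak - max(left_min, right_min).
oracle_peaks <- function(z, min_prominence = 0) {
  n <- length(z)
  cand <- which(diff(sign(diff(z))) < 0) + 1L
  keep <- vapply(cand, function(p) {
    lmin <- z[p]; i <- p
    while (i > 1 && z[i] <= z[p]) { i <- i - 1; lmin <- min(lmin, z[i]) }
    if (z[i] <= z[p]) lmin <- min(z[1:p])
    rmin <- z[p]; j <- p
    while (j < n && z[j] <= z[p]) { j <- j + 1; rmin <- min(rmin, z[j]) }
    if (z[j] <= z[p]) rmin <- min(z[p:n])
    (z[p] - max(lmin, rmin)) >= min_prominence
  }, TRUE)
  cand[keep]
}

# 3-NN majority vote by definition (Euclidean), ties by nearest neighbor.
oracle_knn3 <- function(Xtr, ytr, Xte) {
  apply(Xte, 1, function(q) {
    d <- sqrt(rowSums(sweep(Xtr, 2, q)^2))
    nb <- order(d, seq_along(d))[1:min(3, nrow(Xtr))]
    tab <- table(ytr[nb])
    if (length(tab) == 1 || max(tab) > min(tab)) names(which.max(tab))
    else ytr[nb[1]]
  })
}

# two well-separated Gaussian blobs in 2D with a 9/21 split
make_blob_features <- function(seed, n1 = 9, n2 = 21, gap = 3) {
  set.seed(seed)
  X <- rbind(cbind(rnorm(n1, gap, 0.5), rnorm(n1, gap, 0.5)),
             cbind(rnorm(n2, 0, 0.5), rnorm(n2, 0, 0.5)))
  list(features = data.frame(subject_id = sprintf("S%02d", seq_len(n1 + n2)),
                             mean_step_length_m = X[, 1],
                             speed_to_get_up_mps = X[, 2]),
       labels = c(rep("low", n1), rep("high", n2)))
}

# small fast day configuration used by several tests
tiny_day_config <- function(...) {
  cohort_config(day_duration = 600, ...)
}
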