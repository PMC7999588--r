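#' Statistics configuration
#'
#' @param alpha Family-wise significance level (default 0.05).
#' @param normality_alpha Shapiro-Wilk gate level (default 0.05).
#' @param variance_alpha Variance-ratio (F) gate level (default 0.05).
#' @param n_boot Bootstrap resamples for relative-difference CIs
#'   (default 10000, minimum 1000).
#' @param seed Integer seed for the bootstrap.
#' @return List of class `fw_stat_config`.
#' @export
stat_config <- function(alpha = 0.05, normality_alpha = 0.05,
                        variance_alpha = 0.05, n_boot = 10000, seed = 1) {
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  if (n_boot < 1000) stopf("n_boot must be >= 1000")
  structure(list(alpha = alpha, normality_alpha = normality_alpha,
                 variance_alpha = variance_alpha, n_boot = n_boot,
                 seed = seed), class = "fw_stat_config")
}

#' Choose the two-group test for one parameter
#'
#' Student's t (pooled) when Shapiro-Wilk does not reject normality in either
#' group and the variance-ratio F test does not reject homogeneity; otherwise
#' the Wilcoxon rank-sum test. Groups smaller than 3 fall back to Wilcoxon
#' with a warning. The decision is invariant to group order.
#'
#' @param x,y Numeric vectors (low- and high-risk group values).
#' @param config A [stat_config()].
#' @return `"student_t"` or `"wilcoxon_rank_sum"`.
#' @export
select_test <- function(x, y, config = stat_config()) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 3 || length(y) < 3) {
    warning("group with fewer than 3 values: using Wilcoxon rank-sum")
    return("wilcoxon_rank_sum")
  }
  sw <- function(v) {
    if (length(unique(v)) < 3) return(0)  # constant/degenerate: not normal
    tryCatch(stats::shapiro.test(v)$p.value, error = function(e) 0)
  }
  normal <- sw(x) > config$normality_alpha && sw(y) > config$normality_alpha
  homo <- tryCatch(stats::var.test(x, y)$p.value > config$variance_alpha,
                   error = function(e) FALSE)
  if (normal && homo) "student_t" else "wilcoxon_rank_sum"
}

#' Holm step-down adjustment
#'
#' `adjusted[i] = min(1, max over j with p[j] ranked <= rank(i) of
#' (m - rank(j) + 1) * p[j])`, returned in the input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
holm_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.na(p) & (p < 0 | p > 1))) stopf("p-values must lie in [0, 1]")
  m <- sum(!is.na(p))
  o <- order(p, na.last = TRUE)
  adj <- rep(NA_real_, length(p))
  run <- 0
  for (k in seq_along(o)) {
    i <- o[k]
    if (is.na(p[i])) next
    run <- max(run, (m - k + 1) * p[i])
    adj[i] <- min(1, run)
  }
  adj
}

#' Relative difference between group means with bootstrap CI
#'
#' Point estimate `(mean(y) - mean(x)) / mean(x) * 100` (percent change of the
#' high-risk group relative to the low-risk group) with a seeded percentile
#' bootstrap CI over subjects (groups resampled independently).
#'
#' @param x,y Numeric vectors (reference group `x` first).
#' @param config A [stat_config()] (uses `n_boot`, `seed`).
#' @param conf Confidence level (default 0.95).
#' @return List: `point`, `ci_low`, `ci_high` (percent). All `NA` with a
#'   `flag` when `mean(x)` is 0.
#' @export
relative_difference_ci <- function(x, y, config = stat_config(), conf = 0.95) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (!length(x) || !length(y) || mean(x) == 0)
    return(list(point = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                flag = "undefined: reference mean is 0 or group empty"))
  point <- (mean(y) - mean(x)) / mean(x) * 100
  qs <- with_seed(config$seed, {
    stat <- numeric(config$n_boot)
    for (b in seq_len(config$n_boot)) {
      xb <- x[sample.int(length(x), replace = TRUE)]
      yb <- y[sample.int(length(y), replace = TRUE)]
      stat[b] <- if (mean(xb) == 0) NA_real_ else
        (mean(yb) - mean(xb)) / mean(xb) * 100
    }
    stats::quantile(stat, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                    na.rm = TRUE, names = FALSE)
  })
  list(point = point, ci_low = qs[1], ci_high = qs[2], flag = NULL)
}

#' Two-group comparison of every behavioral parameter
#'
#' For each parameter: test selection ([select_test()]), the chosen two-sided
#' test, Holm adjustment over the family of tested parameters, and the
#' relative difference with bootstrap CI. Parameters missing for more than
#' half of either group are excluded (recorded in attribute `"excluded"`).
#'
#' @param features data.frame with `subject_id` + parameter columns.
#' @param labels Aligned labels (`"low"`/`"high"`).
#' @param config A [stat_config()].
#' @param parameters Parameter columns to test (default all 15 present).
#' @param ci Compute bootstrap CIs for the relative differences (default
#'   TRUE; power simulations that only need the test decisions can skip
#'   them).
#' @return data.frame of class `fw_stats`: one row per tested parameter with
#'   `parameter`, `test_used`, `p_raw`, `p_adjusted`, `significant`,
#'   `relative_difference_pct`, `ci_low_pct`, `ci_high_pct`.
#' @export
compare_all <- function(features, labels, config = stat_config(),
                        parameters = NULL, ci = TRUE) {
  parameters <- parameters %||% intersect(parameter_names(), names(features))
  labels <- as.character(labels)
  if (!all(labels[!is.na(labels)] %in% c("low", "high")))
    stopf("labels must be 'low'/'high'")
  excluded <- character(0)
  rows <- list()
  for (k in seq_along(parameters)) {
    p <- parameters[k]
    x <- features[[p]][labels == "low"]
    y <- features[[p]][labels == "high"]
    if (mean(is.na(x)) > 0.5 || mean(is.na(y)) > 0.5 ||
        sum(is.finite(x)) < 2 || sum(is.finite(y)) < 2) {
      excluded <- c(excluded, p)
      next
    }
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    test <- suppressWarnings(select_test(x, y, config))
    p_raw <- suppressWarnings(if (test == "student_t")
      stats::t.test(x, y, var.equal = TRUE)$p.value
    else stats::wilcox.test(x, y)$p.value)
    rd <- if (ci) {
      ci_cfg <- config; ci_cfg$seed <- derive_seed(config$seed, k)
      relative_difference_ci(x, y, ci_cfg)
    } else list(point = if (mean(x) == 0) NA_real_ else
                  (mean(y) - mean(x)) / mean(x) * 100,
                ci_low = NA_real_, ci_high = NA_real_)
    rows[[length(rows) + 1]] <- data.frame(
      parameter = p, test_used = test, p_raw = p_raw,
      p_adjusted = NA_real_, significant = NA,
      relative_difference_pct = rd$point, ci_low_pct = rd$ci_low,
      ci_high_pct = rd$ci_high, stringsAsFactors = FALSE)
  }
  if (!length(rows)) stopf("no testable parameters")
  out <- do.call(rbind, rows)
  out$p_adjusted <- holm_adjust(out$p_raw)
  out$significant <- out$p_adjusted < config$alpha
  attr(out, "excluded") <- excluded
  class(out) <- c("fw_stats", "data.frame")
  out
}

#' Plot relative group differences with confidence intervals
#'
#' Forest-style base-graphics plot of the per-parameter relative difference
#' (high vs low risk) with 95% CIs; significant parameters are starred.
#'
#' @param stats An `fw_stats` from [compare_all()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot_group_differences <- function(stats, ...) {
  n <- nrow(stats)
  ord <- seq_len(n)
  xlim <- range(c(stats$ci_low_pct, stats$ci_high_pct, 0), na.rm = TRUE)
  graphics::plot(stats$relative_difference_pct, ord, xlim = xlim,
                 yaxt = "n", xlab = "Relative difference (%)", ylab = "",
                 pch = 19, panel.first = graphics::abline(v = 0, lty = 3), ...)
  graphics::segments(stats$ci_low_pct, ord, stats$ci_high_pct, ord)
  lab <- paste0(stats$parameter, ifelse(stats$significant, " *", ""))
  graphics::axis(2, at = ord, labels = lab, las = 2, cex.axis = 0.7)
  invisible(stats)
}
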