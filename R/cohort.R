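#' Cohort configuration
#'
#' Builds the configuration of a synthetic monitored cohort. Defaults
#' reproduce the study design the package emulates: 30 subjects in a
#' transitional-care unit, 9 at low and 21 at high fall risk, monitored for
#' one 8-hour day at 30 Hz.
#'
#' Two separation modes control the group effect structure of the latent
#' behavioral parameters:
#' \describe{
#'   \item{`separable`}{mean step length, get-up speed and sitting budget have
#'     disjoint group supports (truncated at the group midpoint plus/minus half
#'     a margin), guaranteeing a learnable boundary.}
#'   \item{`overlap`}{only mean step length carries a large effect; get-up
#'     speed and sitting budget differ mildly (sub-significant at n = 9/21
#'     after Holm correction over 15 parameters) and all other parameters
#'     differ by less than 0.2 pooled standard deviations.}
#' }
#'
#' @param n_subjects Number of subjects (default 30).
#' @param n_low_risk Number of low-risk subjects (default 9).
#' @param frame_rate Sampling rate of the centroid trajectory, Hz (default 30).
#' @param day_duration Monitored day length in seconds (default 28800 = 8 h).
#' @param separation_mode `"separable"` or `"overlap"`.
#' @param n_incongruent Number of high-risk subjects forced to the
#'   test-incongruent pattern (Tinetti 27, best TUG 17.0 / 17.81 s); at most 2
#'   have distinct published TUG values.
#' @param noise_sd Gaussian noise sd added to trajectory coordinates, meters
#'   (default 0; manual labeling and many-pixel centroids are near noise-free).
#' @param group_distributions Optional list overriding per-parameter
#'   `(mean, sd)` pairs per risk group; see [default_group_distributions()].
#' @param separation_margins Named numeric, absolute support gap per separating
#'   parameter in separable mode.
#' @param room Room size `c(width, depth)` in meters.
#' @return An object of class `fw_cohort_config` (a list).
#' @export
cohort_config <- function(n_subjects = 30, n_low_risk = 9, frame_rate = 30,
                          day_duration = 28800,
                          separation_mode = c("separable", "overlap"),
                          n_incongruent = 0, noise_sd = 0,
                          group_distributions = NULL,
                          separation_margins = c(mean_step_length_m = 0.06,
                                                 speed_to_get_up_mps = 0.05,
                                                 total_sitting_pct = 6),
                          room = c(5, 4)) {
  separation_mode <- match.arg(separation_mode)
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_low_risk = as.integer(n_low_risk),
    frame_rate = frame_rate, day_duration = day_duration,
    separation_mode = separation_mode, n_incongruent = as.integer(n_incongruent),
    noise_sd = noise_sd,
    group_distributions = group_distributions %||%
      default_group_distributions(separation_mode),
    separation_margins = separation_margins, room = room
  )
  class(cfg) <- "fw_cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_low_risk > cfg$n_subjects)
    stopf("invalid config: n_low_risk (%d) > n_subjects (%d)",
          cfg$n_low_risk, cfg$n_subjects)
  if (cfg$frame_rate <= 0) stopf("invalid config: frame_rate must be > 0")
  if (cfg$day_duration <= 0) stopf("invalid config: day_duration must be > 0")
  if (cfg$n_incongruent > cfg$n_subjects - cfg$n_low_risk)
    stopf("invalid config: n_incongruent (%d) exceeds high-risk count (%d)",
          cfg$n_incongruent, cfg$n_subjects - cfg$n_low_risk)
  sds <- unlist(lapply(cfg$group_distributions, function(p) c(p$low[2], p$high[2])))
  if (any(sds < 0)) stopf("invalid config: all sds must be >= 0")
  invisible(cfg)
}

#' Default group-conditional parameter distributions
#'
#' Per-parameter `(mean, sd)` pairs for the low- and high-risk groups that the
#' synthetic generator draws latent subject values from. Magnitudes are
#' calibration choices of the generator (the emulated study reports only
#' directions and significance): step length 0.52 vs 0.36 m, get-up speed 0.30
#' vs 0.17 m/s and sitting budget 35 vs 55% in separable mode; in overlap mode
#' get-up speed and sitting shrink to sub-significant differences and all
#' remaining parameters differ by < 0.2 pooled sd.
#'
#' @param separation_mode `"separable"` or `"overlap"`.
#' @return Named list; each element is `list(low = c(mean, sd), high = c(mean, sd))`.
#' @export
default_group_distributions <- function(separation_mode = "separable") {
  sep <- identical(separation_mode, "separable")
  d <- function(lm, ls, hm, hs) list(low = c(lm, ls), high = c(hm, hs))
  list(
    total_lying_pct      = d(8,    5,    8.8,  5),
    total_sitting_pct    = if (sep) d(35, 8, 55, 8) else d(35, 9, 39, 9),
    out_of_room_pct      = d(15,   8,    16,   8),
    n_transitions        = d(45,   12,   47,   12),
    time_to_sit_s        = d(2.0,  0.5,  2.08, 0.5),
    speed_to_sit_mps     = d(0.25, 0.06, 0.24, 0.06),
    time_to_get_up_s     = if (sep) d(1.35, 0.35, 2.35, 0.55) else d(1.35, 0.5, 1.43, 0.5),
    speed_to_get_up_mps  = if (sep) d(0.30, 0.05, 0.17, 0.04) else d(0.30, 0.05, 0.285, 0.05),
    mean_step_length_m   = d(0.52, 0.05, 0.36, 0.06),
    cv_step_length       = d(0.12, 0.03, 0.125, 0.03),
    mean_step_duration_s = d(0.55, 0.05, 0.555, 0.05),
    cv_step_duration     = d(0.10, 0.03, 0.105, 0.03),
    mean_pace_steps_per_s = d(1.82, 0.15, 1.80, 0.15),
    cv_pace              = d(0.10, 0.03, 0.105, 0.03),
    mean_gait_speed_mps  = d(0.95, 0.15, 0.93, 0.15)
  )
}

# Draw one latent value for `param` and `group` honoring separable-mode
# support truncation. sd 0 yields the mean exactly.
draw_param <- function(cfg, param, group, n = 1) {
  dist <- cfg$group_distributions[[param]]
  m <- dist[[group]][1]; s <- dist[[group]][2]
  lo <- -Inf; hi <- Inf
  if (identical(cfg$separation_mode, "separable") &&
      param %in% names(cfg$separation_margins)) {
    other <- if (group == "low") "high" else "low"
    mid <- (dist$low[1] + dist$high[1]) / 2
    half <- cfg$separation_margins[[param]] / 2
    if (m >= dist[[other]][1]) lo <- mid + half else hi <- mid - half
  }
  # physical floors
  lo <- max(lo, if (grepl("pct", param)) 0 else 1e-3)
  if (s == 0) return(rep(min(max(m, lo), hi), n))
  truncnorm::rtruncnorm(n, a = lo, b = hi, mean = m, sd = s)
}

#' Sample a parameter-level cohort matrix
#'
#' Draws the fifteen behavioral parameters for every subject directly from the
#' group-conditional distributions, without simulating trajectories. This is
#' the stated statistical world of the generator and is what the group-stats
#' power properties operate on. Parameters are drawn independently per subject
#' (no within-subject coupling between, e.g., step length and gait speed).
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return data.frame with `subject_id`, `group` and the 15 parameter columns.
#' @export
sample_parameter_matrix <- function(config, seed) {
  validate_cohort_config(config)
  with_seed(seed, {
    groups <- c(rep("low", config$n_low_risk),
                rep("high", config$n_subjects - config$n_low_risk))
    out <- data.frame(
      subject_id = sprintf("S%02d", seq_len(config$n_subjects)),
      group = groups, stringsAsFactors = FALSE
    )
    for (p in FW_PARAMS) {
      v <- numeric(config$n_subjects)
      for (i in seq_along(groups)) v[i] <- draw_param(config, p, groups[i])
      if (p == "n_transitions") v <- pmax(0, round(v))
      out[[p]] <- v
    }
    out
  })
}

# group-calibrated turn/hesitation constants so simulated TUG group means land
# on the emulated study's descriptives (11.82 s low, 23.52 s high)
tug_turn_defaults <- list(low = c(mean = 2.5, sd = 0.8), high = c(mean = 10.0, sd = 4.0))

simulate_tug_trials <- function(latent, group, n_trials = 3, cutoff = 13.5) {
  walk_t <- 6 / (latent$step_length / latent$step_duration)
  base <- latent$getup_duration + walk_t + latent$sitdown_duration
  turn <- tug_turn_defaults[[group]]
  trials <- numeric(n_trials)
  for (j in seq_len(n_trials)) {
    ok <- FALSE
    for (try in 1:200) {
      t <- base + stats::rnorm(1, turn["mean"], turn["sd"]) + stats::rnorm(1, 0, 0.3)
      if (t > 0 && ((group == "low" && t < cutoff) || (group == "high" && t >= cutoff))) {
        ok <- TRUE; break
      }
    }
    if (!ok) t <- if (group == "low") cutoff - 0.5 else cutoff + 0.5
    trials[j] <- round(t, 2)
  }
  trials
}

#' Generate a synthetic cohort of subject profiles
#'
#' Creates `n_subjects` profiles with true risk group, clinical scores (Tinetti
#' 0-28 and three TUG trial times) and the latent behavioral parameters that
#' drive [simulate_day()]. Clinical scores are drawn consistently with the true
#' group (low: TUG centered 11.82 s, Tinetti centered 26.25; high: 23.52 s and
#' 18.76, truncated to the group-consistent side of the clinical cutoffs) so
#' that the clinical labeling reproduces the true groups. TUG times co-vary
#' with behavior: each trial is the latent get-up duration plus a 6 m walk at
#' the latent gait speed plus a group-calibrated turn/hesitation term plus the
#' sit-down duration plus noise.
#'
#' With `n_incongruent = 2` the last two high-risk subjects are forced to the
#' test-incongruent worked case: Tinetti 27 with best TUG trials 17.0 s and
#' 17.81 s.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; identical `(config, seed)` gives identical cohorts.
#' @return Object of class `fw_cohort`: list with `config` and `subjects`
#'   (list of profile lists).
#' @export
make_cohort <- function(config = cohort_config(), seed = 1) {
  validate_cohort_config(config)
  params <- sample_parameter_matrix(config, derive_seed(seed, 1))
  with_seed(derive_seed(seed, 2), {
    subjects <- vector("list", config$n_subjects)
    n_high <- config$n_subjects - config$n_low_risk
    incongruent_ids <- if (config$n_incongruent > 0)
      utils::tail(which(params$group == "high"), config$n_incongruent) else integer(0)
    incongruent_tug <- c(17.0, 17.81)
    for (i in seq_len(config$n_subjects)) {
      g <- params$group[i]
      row <- params[i, FW_PARAMS]
      excursion <- 0.40
      latent <- list(
        step_length = row$mean_step_length_m,
        step_duration = row$mean_step_duration_s,
        step_length_cv = row$cv_step_length,
        step_duration_cv = row$cv_step_duration,
        getup_speed = row$speed_to_get_up_mps,
        sitdown_speed = row$speed_to_sit_mps,
        excursion = excursion,
        getup_duration = excursion / row$speed_to_get_up_mps,
        sitdown_duration = excursion / row$speed_to_sit_mps,
        budget = c(sitting = row$total_sitting_pct / 100,
                   lying = row$total_lying_pct / 100,
                   out_of_room = row$out_of_room_pct / 100)
      )
      if (i %in% incongruent_ids) {
        k <- match(i, incongruent_ids)
        best <- incongruent_tug[((k - 1) %% 2) + 1]
        tug <- round(best + c(0, abs(stats::rnorm(2, 1.5, 0.8))), 2)
        tinetti <- 27L
      } else {
        tug <- simulate_tug_trials(latent, g)
        tin_dist <- if (g == "low") c(26.25, 1.75) else c(18.76, 4.02)
        rng <- if (g == "low") c(21, 28) else c(0, 28)
        tinetti <- as.integer(round(truncnorm::rtruncnorm(
          1, a = rng[1] - 0.49, b = rng[2] + 0.49,
          mean = tin_dist[1], sd = tin_dist[2])))
        tinetti <- min(max(tinetti, rng[1]), rng[2])
        # with forced incongruent subjects, keep 27 unique to them
        if (config$n_incongruent > 0 && tinetti == 27L)
          tinetti <- if (g == "low") 28L else 26L
      }
      subjects[[i]] <- list(
        subject_id = params$subject_id[i], true_group = g,
        tinetti_score = tinetti, tug_trials = tug,
        fell_before = stats::runif(1) < if (g == "high") 0.5 else 0.1,
        latent = latent,
        latent_params = as.list(row)
      )
    }
    structure(list(config = config, subjects = subjects), class = "fw_cohort")
  })
}

#' @export
print.fw_cohort <- function(x, ...) {
  g <- vapply(x$subjects, `[[`, "", "true_group")
  cat(sprintf("<fw_cohort> %d subjects (%d low / %d high risk), mode=%s\n",
              length(x$subjects), sum(g == "low"), sum(g == "high"),
              x$config$separation_mode))
  invisible(x)
}
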