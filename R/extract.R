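# centered moving average; window in samples (odd), edges use shrinking window
moving_average <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  h <- w %/% 2
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Local maxima with scipy-style prominence and minimum separation.
# Returns sorted indices. Prominence of a peak: height above the higher of the
# two deepest valleys separating it from higher terrain (or the signal edge).
find_peaks <- function(z, min_prominence = 0, min_separation = 0) {
  n <- length(z)
  if (n < 3) return(integer(0))
  cand <- which(z[2:(n - 1)] > z[1:(n - 2)] & z[2:(n - 1)] >= z[3:n]) + 1L
  # drop plateau continuations (equal-height neighbors already counted)
  if (length(cand) > 1) {
    keep <- c(TRUE, z[cand[-1]] != z[cand[-length(cand)]] |
                diff(cand) > 1)
    cand <- cand[keep]
  }
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(p) {
    i <- p; lmin <- z[p]
    while (i > 1 && z[i] <= z[p]) { i <- i - 1; lmin <- min(lmin, z[i]) }
    j <- p; rmin <- z[p]
    while (j < n && z[j] <= z[p]) { j <- j + 1; rmin <- min(rmin, z[j]) }
    lbase <- if (z[i] > z[p]) lmin else min(z[1:p])
    rbase <- if (z[j] > z[p]) rmin else min(z[p:n])
    z[p] - max(lbase, rbase)
  }, 0)
  cand <- cand[prom >= min_prominence]
  if (min_separation > 0 && length(cand) > 1) {
    ord <- cand[order(-z[cand], cand)]
    kept <- integer(0)
    for (p in ord)
      if (!length(kept) || all(abs(kept - p) >= min_separation))
        kept <- c(kept, p)
    cand <- sort(kept)
  }
  cand
}

#' Detect steps in one walking bout
#'
#' A step is the interval between two consecutive local maxima of the vertical
#' centroid coordinate. The z-series is smoothed with a 0.25 s moving average;
#' maxima are retained when their prominence is at least 1 cm and their
#' separation at least 0.2 s (rejecting sensor noise while passing cadences up
#' to 5 steps/s). K retained maxima yield K-1 step events.
#'
#' @param bout data.frame with `time_s`, `x_m`, `y_m`, `z_m` of one contiguous
#'   walking bout (>= 3 samples).
#' @param smooth_window Smoothing window, seconds.
#' @param min_prominence Minimum peak prominence, meters.
#' @param min_separation Minimum peak separation, seconds.
#' @return data.frame of step events: `t_peak_prev`, `t_peak`, `length` (m,
#'   horizontal displacement between the bracketing maxima), `duration` (s).
#'   Zero rows when fewer than two maxima are found.
#' @export
detect_steps <- function(bout, smooth_window = 0.25, min_prominence = 0.01,
                         min_separation = 0.2) {
  stopifnot(nrow(bout) >= 3)
  dt <- stats::median(diff(bout$time_s))
  w <- max(1L, round(smooth_window / dt))
  if (w %% 2 == 0) w <- w + 1L
  zs <- moving_average(bout$z_m, w)
  pk <- find_peaks(zs, min_prominence = min_prominence,
                   min_separation = max(1, round(min_separation / dt)))
  if (length(pk) < 2)
    return(data.frame(t_peak_prev = numeric(), t_peak = numeric(),
                      length = numeric(), duration = numeric()))
  a <- pk[-length(pk)]; b <- pk[-1]
  data.frame(
    t_peak_prev = bout$time_s[a], t_peak = bout$time_s[b],
    length = sqrt((bout$x_m[b] - bout$x_m[a])^2 +
                  (bout$y_m[b] - bout$y_m[a])^2),
    duration = bout$time_s[b] - bout$time_s[a]
  )
}

#' Gait parameters from a day's step events
#'
#' Mean and coefficient of variation of step length and duration, per-step
#' pace (1/duration) mean and CV, and gait speed as total length over total
#' duration (bout-weighted, not the mean of per-step speeds).
#'
#' @param steps data.frame of step events (from [detect_steps()], possibly
#'   concatenated over bouts).
#' @return Named list of the 7 gait fields; all `NA` with fewer than 2 steps.
#' @export
gait_parameters <- function(steps) {
  if (is.null(steps) || nrow(steps) < 2)
    return(list(mean_step_length_m = NA_real_, cv_step_length = NA_real_,
                mean_step_duration_s = NA_real_, cv_step_duration = NA_real_,
                mean_pace_steps_per_s = NA_real_, cv_pace = NA_real_,
                mean_gait_speed_mps = NA_real_))
  pace <- 1 / steps$duration
  list(
    mean_step_length_m = mean(steps$length),
    cv_step_length = coef_var(steps$length),
    mean_step_duration_s = mean(steps$duration),
    cv_step_duration = coef_var(steps$duration),
    mean_pace_steps_per_s = mean(pace),
    cv_pace = coef_var(pace),
    mean_gait_speed_mps = sum(steps$length) / sum(steps$duration)
  )
}

#' Activity-budget parameters from a label sequence
#'
#' Total lying, sitting and out-of-room time as percentages of the monitoring
#' duration, plus the number of transitions (adjacent label changes after
#' collapsing consecutive identical labels).
#'
#' @param labels Character vector of per-sample activity labels.
#' @param day_duration Total monitoring duration, seconds.
#' @param sample_dt Duration represented by one sample, seconds.
#' @param count_out_of_room Count transitions at out-of-room boundaries
#'   (default TRUE; both conventions are defensible, this one is exposed).
#' @return Named list: `total_lying_pct`, `total_sitting_pct`,
#'   `out_of_room_pct`, `n_transitions`.
#' @export
activity_parameters <- function(labels, day_duration, sample_dt,
                                count_out_of_room = TRUE) {
  tot <- function(a) sum(labels == a) * sample_dt
  r <- rle(labels)
  lab <- r$values
  if (!count_out_of_room) {
    keep <- lab != "out_of_room"
    lab <- rle(lab[keep])$values
  }
  list(
    total_lying_pct = 100 * tot("lying") / day_duration,
    total_sitting_pct = 100 * tot("sitting") / day_duration,
    out_of_room_pct = 100 * tot("out_of_room") / day_duration,
    n_transitions = max(0L, length(lab) - 1L)
  )
}

# central-difference vertical velocity on the raw z series (smoothing would
# smear ramp edges and bias transition durations)
vertical_velocity <- function(t, z) {
  n <- length(z)
  v <- rep(NA_real_, n)
  if (n < 3) return(v)
  v[2:(n - 1)] <- (z[3:n] - z[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  v[1] <- v[2]; v[n] <- v[n - 1]
  v
}

#' Sit-stand transition parameters
#'
#' For each label change into or out of sitting, the transition window is the
#' maximal contiguous span around the change where the absolute vertical
#' velocity exceeds `speed_threshold`; duration is the window length and speed
#' the absolute vertical excursion over the window divided by the duration.
#' Per-kind fields are means over all events of that kind.
#'
#' @param trajectory Labeled trajectory data.frame.
#' @param speed_threshold Vertical-velocity threshold, m/s (default 0.05).
#' @return Named list: `time_to_sit_s`, `speed_to_sit_mps`, `time_to_get_up_s`,
#'   `speed_to_get_up_mps`; all `NA` when there is no sitting episode. The
#'   per-event table is attached as attribute `"events"`.
#' @export
transition_parameters <- function(trajectory, speed_threshold = 0.05) {
  lab <- trajectory$activity
  n <- length(lab)
  chg <- which(lab[-1] != lab[-n]) + 1L   # index of first sample of new label
  sit_chg <- chg[lab[chg] == "sitting" | lab[chg - 1] == "sitting"]
  if (!length(sit_chg))
    return(structure(list(time_to_sit_s = NA_real_, speed_to_sit_mps = NA_real_,
                          time_to_get_up_s = NA_real_,
                          speed_to_get_up_mps = NA_real_),
                     events = NULL))
  v <- vertical_velocity(trajectory$time_s, trajectory$z_m)
  fast <- !is.na(v) & abs(v) > speed_threshold
  dt <- stats::median(diff(trajectory$time_s))
  events <- list()
  for (b in sit_chg) {
    kind <- if (lab[b] == "sitting") "sit_down" else "get_up"
    # anchor: the fast sample nearest the boundary within 1 s
    win <- max(1, b - round(1 / dt)):min(n, b + round(1 / dt))
    anchors <- win[fast[win]]
    if (!length(anchors)) next
    a0 <- anchors[which.min(abs(anchors - b))]
    i <- a0; while (i > 1 && fast[i - 1]) i <- i - 1
    j <- a0; while (j < n && fast[j + 1]) j <- j + 1
    dur <- trajectory$time_s[j] - trajectory$time_s[i] + dt
    exc <- abs(trajectory$z_m[j] - trajectory$z_m[i])
    events[[length(events) + 1]] <- data.frame(
      kind = kind, t_start = trajectory$time_s[i], t_end = trajectory$time_s[j],
      duration = dur, vertical_excursion = exc, speed = exc / dur)
  }
  if (!length(events))
    return(structure(list(time_to_sit_s = NA_real_, speed_to_sit_mps = NA_real_,
                          time_to_get_up_s = NA_real_,
                          speed_to_get_up_mps = NA_real_),
                     events = NULL))
  ev <- do.call(rbind, events)
  m <- function(k, col) {
    x <- ev[[col]][ev$kind == k]
    if (length(x)) mean(x) else NA_real_
  }
  structure(list(
    time_to_sit_s = m("sit_down", "duration"),
    speed_to_sit_mps = m("sit_down", "speed"),
    time_to_get_up_s = m("get_up", "duration"),
    speed_to_get_up_mps = m("get_up", "speed")
  ), events = ev)
}

#' Extract the 15 behavioral parameters from a labeled trajectory
#'
#' Composes step detection over all walking bouts, activity-budget accounting
#' and sit-stand transition analysis into one parameter set per subject-day.
#' Missing constituents (no walking, no sitting) yield `NA` fields that are
#' excluded pairwise downstream.
#'
#' @param trajectory Labeled trajectory data.frame
#'   (`time_s, x_m, y_m, z_m, activity`).
#' @param day_duration Monitoring duration, seconds; defaults to the trajectory
#'   span plus one sample.
#' @param ... Passed on to [detect_steps()] and [transition_parameters()].
#' @return Named list with the 15 parameters in canonical order
#'   ([parameter_names()]). The step-event table is attached as attribute
#'   `"steps"`.
#' @export
extract_parameters <- function(trajectory, day_duration = NULL, ...) {
  stopifnot(all(c("time_s", "x_m", "y_m", "z_m", "activity") %in%
                names(trajectory)))
  dt <- stats::median(diff(trajectory$time_s))
  if (is.null(day_duration))
    day_duration <- max(trajectory$time_s) - min(trajectory$time_s) + dt
  act <- activity_parameters(trajectory$activity, day_duration, dt)
  dots <- list(...)
  step_args <- dots[names(dots) %in%
                    c("smooth_window", "min_prominence", "min_separation")]
  tr_args <- dots[names(dots) %in% "speed_threshold"]
  r <- rle(trajectory$activity)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  steps <- list()
  for (k in which(r$values == "walking")) {
    if (r$lengths[k] < 3) next
    bout <- trajectory[starts[k]:ends[k], ]
    s <- do.call(detect_steps, c(list(bout), step_args))
    if (nrow(s)) steps[[length(steps) + 1]] <- s
  }
  steps <- if (length(steps)) do.call(rbind, steps) else NULL
  gait <- gait_parameters(steps)
  trans <- do.call(transition_parameters, c(list(trajectory), tr_args))
  out <- c(act, trans[c("time_to_sit_s", "speed_to_sit_mps",
                        "time_to_get_up_s", "speed_to_get_up_mps")], gait)
  structure(out[FW_PARAMS], steps = steps)
}

#' Extract a feature table for a whole simulated cohort
#'
#' Simulates (or accepts pre-simulated) one day per subject and extracts the
#' 15-parameter feature vector for each, one row per subject.
#'
#' @param cohort An `fw_cohort` from [make_cohort()].
#' @param seed Integer master seed; per-subject day seeds are derived
#'   deterministically.
#' @param days Optional pre-simulated list of [simulate_day()] results.
#' @return data.frame: `subject_id` plus the 15 parameter columns. Ground
#'   truths are attached as attribute `"truth"` (list per subject).
#' @export
extract_cohort <- function(cohort, seed = 1, days = NULL) {
  subs <- cohort$subjects
  rows <- vector("list", length(subs))
  truths <- vector("list", length(subs))
  for (i in seq_along(subs)) {
    day <- if (!is.null(days)) days[[i]] else
      simulate_day(subs[[i]], cohort$config, derive_seed(seed, 100 + i))
    p <- extract_parameters(day$trajectory,
                            day_duration = cohort$config$day_duration)
    rows[[i]] <- data.frame(subject_id = subs[[i]]$subject_id,
                            as.data.frame(p), stringsAsFactors = FALSE)
    truths[[i]] <- day$truth
  }
  structure(do.call(rbind, rows), truth = truths)
}
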