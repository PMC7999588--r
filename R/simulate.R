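# Centroid heights of the simulated person, meters. The vertical centroid of a
# standing adult sits near 1 m; sitting drops it ~0.4 m and lying ~0.75 m.
Z_STAND <- 1.00
Z_SIT <- 0.60
Z_LIE <- 0.25
STEP_AMPLITUDE <- 0.06   # peak-to-trough vertical oscillation per step, m
PAUSE_S <- 1.5           # structural standing pause around sit/lie episodes
DWELL_MIN <- 30          # s, lower truncation of drawn dwell times
DWELL_MAX <- 7200        # s (2 h), upper truncation

# exponential dwell truncated to [DWELL_MIN, DWELL_MAX]
rdwell <- function(mean) {
  for (i in 1:50) {
    d <- stats::rexp(1, 1 / mean)
    if (d >= DWELL_MIN && d <= DWELL_MAX) return(d)
  }
  min(max(mean, DWELL_MIN), DWELL_MAX)
}

# Build the day's semi-Markov schedule: alternating walking bouts and station
# episodes; sitting/lying/out station time tracks the latent budgets
# (largest-deficit choice, dwell clipped to the remaining deficit), walking and
# standing absorb the slack. Sitting and lying episodes are bracketed by short
# standing pauses so transition ramps are flanked by quiet vertical signal.
build_schedule <- function(profile, config) {
  D <- config$day_duration
  budget <- profile$latent$budget
  deficit <- c(sitting = unname(budget["sitting"]) * D,
               lying = unname(budget["lying"]) * D,
               out_of_room = unname(budget["out_of_room"]) * D)
  lat <- profile$latent
  min_sit <- lat$sitdown_duration + lat$getup_duration + 5
  segs <- list()
  t <- 0
  add <- function(state, dur) {
    dur <- min(dur, D - t)
    if (dur <= 0) return(FALSE)
    segs[[length(segs) + 1]] <<- list(state = state, start = t, end = t + dur)
    t <<- t + dur
    TRUE
  }
  if (D < 4 * DWELL_MIN)
    stopf("invalid config: day_duration %.0f s too short to host activity bouts", D)
  repeat {
    if (t >= D) break
    # walking bout (>= 3 steps; mean ~60 s)
    wd <- min(max(stats::rexp(1, 1 / 60), 4 * lat$step_duration), 300)
    add("walking", wd)
    if (t >= D) break
    # choose next station by largest remaining budget deficit
    cand <- deficit[deficit > 1]
    if (length(cand) == 0) {
      add("standing", rdwell(120))
      next
    }
    st <- names(cand)[which.max(cand)]
    if (st == "out_of_room") {
      dur <- min(rdwell(deficit["out_of_room"] / 2 + DWELL_MIN), deficit["out_of_room"])
      if (add("out_of_room", dur)) deficit["out_of_room"] <- deficit["out_of_room"] - dur
    } else {
      dur <- min(rdwell(deficit[st] / 2 + DWELL_MIN), deficit[st])
      dur <- max(dur, min_sit)
      if (!add("standing", PAUSE_S)) break
      ok <- add(st, dur)
      if (ok) deficit[st] <- deficit[st] -
          (segs[[length(segs)]]$end - segs[[length(segs)]]$start)
      add("standing", PAUSE_S)
    }
  }
  do.call(rbind, lapply(segs, function(s)
    data.frame(state = s$state, start = s$start, end = s$end,
               stringsAsFactors = FALSE)))
}

# Realize one walking bout: per-step durations/lengths from the subject's
# latent means and CVs; one vertical-oscillation cycle per step with peaks at
# the drawn step boundaries; horizontal displacement per step equals the drawn
# length along a slowly turning heading confined to the room.
realize_walk <- function(seg, lat, start_pos, heading, room) {
  dur <- seg$end - seg$start
  k <- max(3, round(dur / lat$step_duration))
  sd_d <- lat$step_duration_cv * lat$step_duration
  sd_l <- lat$step_length_cv * lat$step_length
  d <- pmax(0.4 * lat$step_duration,
            stats::rnorm(k, lat$step_duration, sd_d))
  # trim steps to fit the segment (keep >= 3)
  while (length(d) > 3 && sum(d) > dur) d <- d[-length(d)]
  k <- length(d)
  l <- pmax(0.05, stats::rnorm(k, lat$step_length, sd_l))
  peaks <- seg$start + cumsum(d)
  lo <- c(0.3, 0.3); hi <- room - 0.3
  pos <- matrix(NA_real_, k + 1, 2)
  pos[1, ] <- start_pos
  for (i in seq_len(k)) {
    for (try in 1:30) {
      cand <- pos[i, ] + l[i] * c(cos(heading), sin(heading))
      if (all(cand >= lo & cand <= hi)) break
      ctr <- room / 2
      heading <- atan2(ctr[2] - pos[i, 2], ctr[1] - pos[i, 1]) +
        stats::rnorm(1, 0, 0.3)
    }
    cand <- pos[i, ] + l[i] * c(cos(heading), sin(heading))
    cand <- pmin(pmax(cand, lo), hi)
    pos[i + 1, ] <- cand
    heading <- heading + stats::rnorm(1, 0, 0.25)
  }
  # ground truth records realized horizontal displacements (wall clamping can
  # shorten a drawn length)
  realized <- sqrt(rowSums((pos[-1, , drop = FALSE] -
                            pos[-(k + 1), , drop = FALSE])^2))
  list(steps = data.frame(length = realized, duration = d),
       peaks = peaks, node_pos = pos, heading = heading,
       end_pos = pos[k + 1, ])
}

# z profile of a walking bout at sample times tt (within the segment):
# piecewise cosine between consecutive peaks, linear lead-in from the standing
# level to the first peak, cosine decay back to standing level after the last.
walk_z <- function(tt, seg_start, peaks) {
  a <- STEP_AMPLITUDE / 2
  z <- rep(Z_STAND, length(tt))
  lead <- tt <= peaks[1]
  z[lead] <- Z_STAND + a * (tt[lead] - seg_start) / max(peaks[1] - seg_start, 1e-9)
  if (length(peaks) > 1) {
    mid <- tt > peaks[1] & tt <= peaks[length(peaks)]
    if (any(mid)) {
      i <- findInterval(tt[mid], peaks, rightmost.closed = FALSE)
      p0 <- peaks[i]; p1 <- peaks[i + 1]
      z[mid] <- Z_STAND + a * cos(2 * pi * (tt[mid] - p0) / (p1 - p0))
    }
  }
  tail <- tt > peaks[length(peaks)]
  if (any(tail)) {
    rel <- pmin((tt[tail] - peaks[length(peaks)]) / 0.4, 1)
    z[tail] <- Z_STAND + a * (1 - rel)  # linear decay back to standing level
  }
  z
}

#' Simulate one monitored day for a subject
#'
#' Generates the labeled 3D centroid trajectory of an 8-hour (configurable)
#' day as a semi-Markov schedule over walking, standing, sitting, lying and
#' out-of-room states, together with full ground truth. Walking bouts realize
#' each drawn step as one vertical-oscillation cycle whose peak-to-peak
#' interval is the step duration and whose horizontal displacement is the step
#' length; sitting and lying episodes begin and end with monotone vertical
#' ramps of the latent excursion over the latent transition duration.
#'
#' @param profile One subject profile from [make_cohort()].
#' @param config The [cohort_config()] used for the cohort.
#' @param seed Integer seed; identical `(profile, config, seed)` yields a
#'   bit-identical trajectory.
#' @return List with `trajectory` (data.frame `time_s, x_m, y_m, z_m, activity`;
#'   coordinates are `NA` when out of room) and `truth` (list: `steps`,
#'   `transitions`, `totals`, `schedule`).
#' @export
simulate_day <- function(profile, config, seed = 1) {
  with_seed(seed, {
    sched <- build_schedule(profile, config)
    lat <- profile$latent
    fps <- config$frame_rate
    n <- floor(config$day_duration * fps)
    times <- (seq_len(n) - 1) / fps
    x <- numeric(n); y <- numeric(n); z <- numeric(n)
    act <- character(n)
    seg_idx <- findInterval(times, sched$start)
    pos <- config$room / 2
    heading <- stats::runif(1, 0, 2 * pi)
    steps_all <- list(); trans_all <- list()
    lie_speed <- lat$sitdown_speed  # lying ramps reuse sit speeds (unmeasured)
    for (s in seq_len(nrow(sched))) {
      idx <- which(seg_idx == s)
      st <- sched$state[s]
      tt <- times[idx]
      act[idx] <- st
      if (st == "walking") {
        w <- realize_walk(sched[s, ], lat, pos, heading, config$room)
        heading <- w$heading
        if (length(idx)) {
          z[idx] <- walk_z(tt, sched$start[s], w$peaks)
          nodes_t <- c(sched$start[s], w$peaks)
          x[idx] <- stats::approx(nodes_t, w$node_pos[, 1], tt, rule = 2)$y
          y[idx] <- stats::approx(nodes_t, w$node_pos[, 2], tt, rule = 2)$y
        }
        pos <- w$end_pos
        steps_all[[length(steps_all) + 1]] <-
          cbind(bout = s, w$steps, t_peak = w$peaks)
      } else if (st == "standing") {
        z[idx] <- Z_STAND; x[idx] <- pos[1]; y[idx] <- pos[2]
      } else if (st == "out_of_room") {
        x[idx] <- NA_real_; y[idx] <- NA_real_; z[idx] <- NA_real_
      } else { # sitting or lying
        z_low <- if (st == "sitting") Z_SIT else Z_LIE
        exc <- Z_STAND - z_low
        down_d <- if (st == "sitting") lat$sitdown_duration else exc / lie_speed
        up_d <- if (st == "sitting") lat$getup_duration else exc / lie_speed
        t0 <- sched$start[s]; t1 <- sched$end[s]
        down_d <- min(down_d, (t1 - t0) / 3)
        up_d <- min(up_d, (t1 - t0) / 3)
        zz <- rep(z_low, length(idx))
        in_down <- tt < t0 + down_d
        zz[in_down] <- Z_STAND - exc * (tt[in_down] - t0) / down_d
        in_up <- tt > t1 - up_d
        zz[in_up] <- z_low + exc * (tt[in_up] - (t1 - up_d)) / up_d
        z[idx] <- zz; x[idx] <- pos[1]; y[idx] <- pos[2]
        if (st == "sitting") {
          trans_all[[length(trans_all) + 1]] <- data.frame(
            kind = c("sit_down", "get_up"), t_change = c(t0, t1),
            duration = c(down_d, up_d), excursion = exc,
            speed = exc / c(down_d, up_d))
        }
      }
    }
    if (config$noise_sd > 0) {
      ok <- !is.na(z)
      z[ok] <- z[ok] + stats::rnorm(sum(ok), 0, config$noise_sd)
      x[ok] <- x[ok] + stats::rnorm(sum(ok), 0, config$noise_sd)
      y[ok] <- y[ok] + stats::rnorm(sum(ok), 0, config$noise_sd)
    }
    totals <- vapply(FW_ACTIVITIES, function(a)
      sum(sched$end[sched$state == a] - sched$start[sched$state == a]), 0)
    traj <- data.frame(time_s = times, x_m = x, y_m = y, z_m = z,
                       activity = act, stringsAsFactors = FALSE)
    truth <- list(
      steps = if (length(steps_all)) do.call(rbind, steps_all) else
        data.frame(bout = integer(), length = numeric(), duration = numeric(),
                   t_peak = numeric()),
      transitions = if (length(trans_all)) do.call(rbind, trans_all) else
        data.frame(kind = character(), t_change = numeric(),
                   duration = numeric(), excursion = numeric(), speed = numeric()),
      totals = totals, schedule = sched
    )
    list(trajectory = traj, truth = truth)
  })
}
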