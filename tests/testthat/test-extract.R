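mk_bout <- function(z, dt = 1 / 30, x = NULL) {
  n <- length(z)
  if (is.null(x)) x <- seq(0, by = 0.01, length.out = n)
  data.frame(time_s = (seq_len(n) - 1) * dt,
             x_m = x,
             y_m = rep(1, n), z_m = z,
             activity = rep("walking", n), stringsAsFactors = FALSE)
}

test_that("detect_steps turns K maxima into K-1 steps", {
  # constant z: no steps
  expect_equal(nrow(detect_steps(mk_bout(rep(1, 200)))), 0)
  # sinusoid with 5 cycles -> 5 maxima -> 4 steps
  t <- seq(0, 5 - 1 / 30, by = 1 / 30)
  z <- 1 + 0.03 * cos(2 * pi * (t - 0.5))  # 5 interior peaks at t = 0.5..4.5
  st <- detect_steps(mk_bout(z, dt = 1 / 30))
  expect_equal(nrow(st), 4)
  expect_equal(st$duration, rep(1, 4), tolerance = 0.05)
  # sub-prominence oscillation rejected
  z2 <- 1 + 0.002 * cos(2 * pi * (t - 0.5))
  expect_equal(nrow(detect_steps(mk_bout(z2))), 0)
})

test_that("detected step durations match generated durations", {
  cfg <- tiny_day_config()
  co <- make_cohort(cfg, seed = 8)
  prof <- co$subjects[[1]]
  prof$latent$step_duration <- 0.55
  prof$latent$step_duration_cv <- 0
  prof$latent$step_length_cv <- 0
  day <- simulate_day(prof, cfg, seed = 2)
  sched <- day$truth$schedule
  w <- which(sched$state == "walking")[2]
  idx <- day$trajectory$time_s >= sched$start[w] &
    day$trajectory$time_s < sched$end[w]
  st <- detect_steps(day$trajectory[idx, ])
  n_gen <- sum(day$truth$steps$bout == w)
  expect_equal(nrow(st), n_gen - 1)
  expect_equal(mean(st$duration), 0.55, tolerance = 0.02)
})

test_that("gait parameter arithmetic", {
  same <- data.frame(length = rep(0.5, 4), duration = rep(0.5, 4))
  g <- gait_parameters(same)
  expect_equal(g$mean_step_length_m, 0.5)
  expect_equal(g$mean_step_duration_s, 0.5)
  expect_equal(g$cv_step_length, 0)
  expect_equal(g$cv_pace, 0)
  expect_equal(g$mean_pace_steps_per_s, 2)
  expect_equal(g$mean_gait_speed_mps, 1)

  two <- data.frame(length = c(0.4, 0.6), duration = c(0.5, 0.5))
  g2 <- gait_parameters(two)
  expect_equal(g2$mean_step_length_m, 0.5)
  expect_equal(g2$mean_gait_speed_mps, 1)

  expect_true(is.na(gait_parameters(two[1, ])$mean_step_length_m))
})

test_that("activity budget accounting", {
  lab <- c(rep("sitting", 400), rep("walking", 400))
  a <- activity_parameters(lab, day_duration = 800, sample_dt = 1)
  expect_equal(a$total_sitting_pct, 50)
  expect_equal(a$n_transitions, 1)

  a2 <- activity_parameters(c("sitting", "walking", "sitting"), 3, 1)
  expect_equal(a2$n_transitions, 2)

  a3 <- activity_parameters(rep("out_of_room", 100), 100, 1)
  expect_equal(a3$out_of_room_pct, 100)
  expect_equal(a3$total_sitting_pct, 0)

  # percentages + walking/standing complement always total 100
  set.seed(1)
  lab4 <- sample(c("walking", "standing", "sitting", "lying", "out_of_room"),
                 500, replace = TRUE)
  a4 <- activity_parameters(lab4, 500, 1)
  walkstand <- 100 * mean(lab4 %in% c("walking", "standing"))
  expect_equal(a4$total_lying_pct + a4$total_sitting_pct +
                 a4$out_of_room_pct + walkstand, 100)
})

test_that("transition window recovers ramp duration and speed", {
  dt <- 1 / 30
  # stand 3 s, ramp down 0.4 m over 2 s, sit 5 s, ramp up, stand 3 s
  seg <- function(z, n, act) list(z = z, n = n, act = act)
  parts <- list(
    seg(function(i, n) rep(1, n), 90, "standing"),
    seg(function(i, n) 1 - 0.4 * (seq_len(n) / n), 60, "sitting"),
    seg(function(i, n) rep(0.6, n), 150, "sitting"),
    seg(function(i, n) 0.6 + 0.4 * (seq_len(n) / n), 60, "sitting"),
    seg(function(i, n) rep(1, n), 90, "standing"))
  z <- unlist(lapply(parts, function(p) p$z(NULL, p$n)))
  act <- unlist(lapply(parts, function(p) rep(p$act, p$n)))
  n <- length(z)
  traj <- data.frame(time_s = (seq_len(n) - 1) * dt, x_m = 1, y_m = 1,
                     z_m = z, activity = act, stringsAsFactors = FALSE)
  tr <- transition_parameters(traj)
  expect_equal(tr$time_to_sit_s, 2.0, tolerance = 0.1)
  expect_equal(tr$speed_to_sit_mps, 0.2, tolerance = 0.02)
  expect_equal(tr$time_to_get_up_s, 2.0, tolerance = 0.1)
  # symmetric ramps: sit-down and get-up speeds agree
  expect_equal(tr$speed_to_sit_mps, tr$speed_to_get_up_mps, tolerance = 0.02)

  # no sitting: all transition fields missing
  traj2 <- traj; traj2$activity <- "standing"
  expect_true(is.na(transition_parameters(traj2)$time_to_sit_s))
})

test_that("extract_parameters populates all 15 fields on a synthetic day", {
  cfg <- tiny_day_config()
  co <- make_cohort(cfg, seed = 10)
  day <- simulate_day(co$subjects[[4]], cfg, seed = 3)
  p <- extract_parameters(day$trajectory, day_duration = cfg$day_duration)
  expect_named(p, parameter_names())
  expect_true(all(!is.na(unlist(p))))
  expect_true(p$total_lying_pct + p$total_sitting_pct + p$out_of_room_pct <= 100)

  # day without walking: gait missing, budgets still populated
  keep <- day$trajectory$activity != "walking"
  p2 <- extract_parameters(day$trajectory[keep, ],
                           day_duration = cfg$day_duration)
  expect_true(is.na(p2$mean_step_length_m))
  expect_false(is.na(p2$total_sitting_pct))
})

test_that("horizontal rescaling scales lengths and speeds, fixes durations", {
  cfg <- tiny_day_config()
  co <- make_cohort(cfg, seed = 12)
  day <- simulate_day(co$subjects[[5]], cfg, seed = 4)
  p1 <- extract_parameters(day$trajectory, day_duration = cfg$day_duration)
  scaled <- day$trajectory
  scaled$x_m <- 2 * scaled$x_m; scaled$y_m <- 2 * scaled$y_m
  p2 <- extract_parameters(scaled, day_duration = cfg$day_duration)
  expect_equal(p2$mean_step_length_m, 2 * p1$mean_step_length_m)
  expect_equal(p2$mean_gait_speed_mps, 2 * p1$mean_gait_speed_mps)
  expect_equal(p2$cv_step_length, p1$cv_step_length)
  expect_equal(p2$mean_step_duration_s, p1$mean_step_duration_s)
  expect_equal(p2$time_to_get_up_s, p1$time_to_get_up_s)
})

test_that("extraction recovers generator ground truth per subject", {
  cfg <- tiny_day_config()
  co <- make_cohort(cfg, seed = 21)
  for (i in c(1, 15)) {
    day <- simulate_day(co$subjects[[i]], cfg, seed = 50 + i)
    p <- extract_parameters(day$trajectory, day_duration = cfg$day_duration)
    expect_equal(p$mean_step_length_m, mean(day$truth$steps$length),
                 tolerance = 0.02)
    tru_up <- mean(day$truth$transitions$speed[
      day$truth$transitions$kind == "get_up"])
    expect_equal(p$speed_to_get_up_mps, tru_up,
                 tolerance = 0.15 * tru_up)
  }
})

test_that("centroid series from rendered depth frames", {
  cam <- camera_model()
  traj <- data.frame(
    time_s = (0:2) / 30,
    x_m = c(2.5, 2.55, NA), y_m = c(2.0, 2.0, NA), z_m = c(1.0, 1.0, NA),
    activity = c("walking", "walking", "out_of_room"),
    stringsAsFactors = FALSE)
  ds <- render_depth_sequence(traj, cam, noise_sd_mm = 0, seed = 1)
  # out-of-room renders as pure background
  expect_identical(ds$frames[[3]], ds$background)
  rec <- extract_centroid_series(ds)
  expect_equal(rec$activity[3], "out_of_room")
  for (i in 1:2) {
    err <- sqrt((rec$x_m[i] - traj$x_m[i])^2 + (rec$y_m[i] - traj$y_m[i])^2 +
                (rec$z_m[i] - traj$z_m[i])^2)
    expect_lt(err, 0.01)
  }
  # mismatched dimensions are a format error
  ds_bad <- ds; ds_bad$frames[[1]] <- ds$frames[[1]][-1, ]
  expect_error(extract_centroid_series(ds_bad), "dimensions")
})

test_that("two disjoint equal blobs average near their midpoint", {
  cam <- camera_model()
  bg <- fallwatch:::render_background(cam)
  blob <- function(rows, cols) {
    fr <- bg; fr[rows, cols] <- 2000; fr   # constant-depth patches
  }
  mk <- function(frames) structure(
    list(frames = frames, timestamps = seq_along(frames) / 30, camera = cam,
         background = bg), class = "fw_depth_sequence")
  # columns symmetric about the image center so the blobs sit at equal depth
  a <- extract_centroid_series(mk(list(blob(40:59, 55:69))))
  b <- extract_centroid_series(mk(list(blob(40:59, 92:106))))
  both <- extract_centroid_series(mk(list(blob(40:59, c(55:69, 92:106)))))
  mid <- (as.numeric(a[1, 2:4]) + as.numeric(b[1, 2:4])) / 2
  expect_lt(sqrt(sum((as.numeric(both[1, 2:4]) - mid)^2)), 0.05)
})
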