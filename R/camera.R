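#' Camera model for depth rendering
#'
#' Pinhole depth camera in a room corner, tilted below the horizontal, looking
#' toward the room center. Depth values are Euclidean distances along the
#' pixel ray, in millimeters (time-of-flight convention).
#'
#' @param position 3D camera position in world meters (default corner, 2.2 m
#'   high).
#' @param tilt_deg Tilt below horizontal, degrees, in (0, 90) (default 20).
#' @param image_size `c(width, height)` in pixels (default 160 x 120; a
#'   down-scaled sensor keeps rendering cheap).
#' @param focal_px Focal length in pixels (default 120).
#' @param depth_range_mm Valid depth range (default `c(500, 8000)`).
#' @param room Room size `c(width, depth)` in meters, ceiling at 2.5 m.
#' @return List of class `fw_camera` including the world-from-camera rotation.
#' @export
camera_model <- function(position = c(0.05, 0.05, 2.2), tilt_deg = 20,
                         image_size = c(160, 120), focal_px = 120,
                         depth_range_mm = c(500, 8000), room = c(5, 4)) {
  if (tilt_deg <= 0 || tilt_deg >= 90) stopf("tilt must be in (0, 90) degrees")
  if (any(image_size <= 0)) stopf("image dimensions must be > 0")
  yaw <- atan2(room[2] / 2 - position[2], room[1] / 2 - position[1])
  tilt <- tilt_deg * pi / 180
  # camera axes in world coordinates: fwd = optical axis, right, down
  fwd <- c(cos(yaw) * cos(tilt), sin(yaw) * cos(tilt), -sin(tilt))
  right <- c(-sin(yaw), cos(yaw), 0)
  down <- c(-cos(yaw) * sin(tilt), -sin(yaw) * sin(tilt), -cos(tilt))
  structure(list(position = position, tilt_deg = tilt_deg,
                 image_size = as.integer(image_size), focal_px = focal_px,
                 depth_range_mm = depth_range_mm, room = room,
                 R = rbind(fwd, right, down)), class = "fw_camera")
}

# distance along each pixel ray to the room box exit (floor z=0, walls,
# ceiling); the empty-room background depth in mm
render_background <- function(camera, ceiling = 2.5) {
  W <- camera$image_size[1]; H <- camera$image_size[2]
  u <- rep(seq_len(W) - (W + 1) / 2, times = H)
  v <- rep(seq_len(H) - (H + 1) / 2, each = W)
  dc <- rbind(camera$focal_px, u, v)
  dw <- t(camera$R) %*% dc
  nrm <- sqrt(colSums(dw^2))
  dw <- sweep(dw, 2, nrm, "/")
  o <- camera$position
  lims <- rbind(c(0, camera$room[1]), c(0, camera$room[2]), c(0, ceiling))
  tmax <- rep(Inf, ncol(dw))
  for (ax in 1:3) for (side in 1:2) {
    tt <- (lims[ax, side] - o[ax]) / dw[ax, ]
    ok <- is.finite(tt) & tt > 1e-6
    if (!any(ok)) next
    p <- sweep(sweep(dw[, ok, drop = FALSE], 2, tt[ok], "*"), 1, o, "+")
    oth <- setdiff(1:3, ax)
    inside <- p[oth[1], ] >= lims[oth[1], 1] - 1e-9 &
      p[oth[1], ] <= lims[oth[1], 2] + 1e-9 &
      p[oth[2], ] >= lims[oth[2], 1] - 1e-9 &
      p[oth[2], ] <= lims[oth[2], 2] + 1e-9
    idx <- which(ok)[inside]
    tmax[idx] <- pmin(tmax[idx], tt[idx])
  }
  tmax[!is.finite(tmax)] <- camera$depth_range_mm[2] / 1000
  matrix(as.integer(round(tmax * 1000)), nrow = H, ncol = W, byrow = TRUE)
}

# Renders the person as an axis-aligned ellipsoidal blob (default: sphere of
# radius 0.3 m, for which the tangent silhouette is symmetric about the
# centroid direction and centroid recovery is unbiased; elongated blobs
# acquire a small perspective bias). Returns depth matrix in mm or NULL when
# nothing is visible.
render_person <- function(camera, centroid, half_axes = c(0.3, 0.3, 0.3)) {
  W <- camera$image_size[1]; H <- camera$image_size[2]
  u <- rep(seq_len(W) - (W + 1) / 2, times = H)
  v <- rep(seq_len(H) - (H + 1) / 2, each = W)
  dc <- rbind(camera$focal_px, u, v)
  dw <- t(camera$R) %*% dc
  nrm <- sqrt(colSums(dw^2))
  dw <- sweep(dw, 2, nrm, "/")
  o <- (camera$position - centroid) / half_axes
  dd <- dw / half_axes
  A <- colSums(dd^2)
  B <- 2 * colSums(dd * o)
  C <- sum(o^2) - 1
  disc <- B^2 - 4 * A * C
  hit <- disc > 0 & -B / (2 * A) > 0
  if (!any(hit)) return(NULL)
  # Hit pixels store the distance to the plane through the centroid
  # perpendicular to the centroid viewing direction ("body mid-depth"): the
  # along-axis component of every back-projected pixel is then exact, so the
  # foreground mean recovers the centroid. A real ToF sensor would see the
  # front surface instead; this stylization is documented as non-emulated.
  a_dir <- centroid - camera$position
  D <- sqrt(sum(a_dir^2))
  a_dir <- a_dir / D
  tmid <- rep(NA_real_, length(A))
  ca <- colSums(dw * a_dir)[hit]
  tmid[hit] <- ifelse(ca > 1e-6, D / ca, NA)
  matrix(as.integer(round(tmid * 1000)), nrow = H, ncol = W, byrow = TRUE)
}

#' Render a depth-frame sequence from a trajectory
#'
#' Produces one synthetic depth frame per trajectory sample: the empty-room
#' background with an ellipsoidal person blob centered on the centroid,
#' projected through the tilted corner camera, plus optional zero-mean depth
#' noise. Out-of-room samples render as pure background; centroids outside
#' the camera frustum trigger a warning and render as background.
#'
#' @param trajectory Labeled trajectory data.frame (a subset of rows is
#'   usually rendered; full days are large).
#' @param camera A [camera_model()].
#' @param noise_sd_mm Depth noise sd in mm (default 10).
#' @param seed Seed for the noise.
#' @return List of class `fw_depth_sequence`: `frames` (list of integer mm
#'   matrices), `timestamps`, `camera`, `background`.
#' @export
render_depth_sequence <- function(trajectory, camera = camera_model(),
                                  noise_sd_mm = 10, seed = 1) {
  bg <- render_background(camera)
  with_seed(seed, {
    frames <- vector("list", nrow(trajectory))
    ts <- trajectory$time_s
    for (i in seq_len(nrow(trajectory))) {
      fr <- bg
      if (!is.na(trajectory$z_m[i]) &&
          !identical(trajectory$activity[i], "out_of_room")) {
        person <- render_person(camera, c(trajectory$x_m[i],
                                          trajectory$y_m[i],
                                          trajectory$z_m[i]))
        if (is.null(person) || !any(!is.na(person))) {
          warning(sprintf("frame %d: centroid outside camera frustum; rendered as background", i))
        } else {
          vis <- !is.na(person) & person < fr
          fr[vis] <- person[vis]
        }
      }
      if (noise_sd_mm > 0)
        fr <- fr + matrix(as.integer(round(stats::rnorm(length(fr), 0,
                                                        noise_sd_mm))),
                          nrow(fr), ncol(fr))
      frames[[i]] <- pmax(fr, 0L)
    }
    structure(list(frames = frames, timestamps = ts, camera = camera,
                   background = bg), class = "fw_depth_sequence")
  })
}

#' Recover the centroid trajectory from depth frames
#'
#' Per frame, foreground pixels are those whose depth differs from the
#' background by more than `threshold_mm`; frames with fewer than
#' `min_pixels` foreground pixels are marked out-of-room. Otherwise the
#' centroid is the mean of the foreground pixels back-projected to world
#' coordinates through the camera model (single-person assumption: two
#' disjoint blobs average to their midpoint).
#'
#' @param depth An `fw_depth_sequence`.
#' @param threshold_mm Foreground depth-difference threshold (default 150 mm).
#' @param min_pixels Minimum foreground pixel count (default 12).
#' @return Trajectory data.frame (`time_s, x_m, y_m, z_m, activity`) with
#'   `activity` set to `"out_of_room"` for empty frames and `NA` otherwise
#'   (activity labels are not recoverable from depth alone).
#' @export
extract_centroid_series <- function(depth, threshold_mm = 150, min_pixels = 12) {
  cam <- depth$camera
  bg <- depth$background
  W <- cam$image_size[1]; H <- cam$image_size[2]
  u_px <- matrix(rep(seq_len(W) - (W + 1) / 2, times = H), H, W, byrow = TRUE)
  v_px <- matrix(rep(seq_len(H) - (H + 1) / 2, each = W), H, W, byrow = TRUE)
  out <- data.frame(time_s = depth$timestamps, x_m = NA_real_, y_m = NA_real_,
                    z_m = NA_real_, activity = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(depth$frames)) {
    fr <- depth$frames[[i]]
    if (!all(dim(fr) == dim(bg)))
      stopf("frame %d dimensions %s do not match background %s", i,
            paste(dim(fr), collapse = "x"), paste(dim(bg), collapse = "x"))
    fg <- abs(fr - bg) > threshold_mm
    if (sum(fg) < min_pixels) {
      out$activity[i] <- "out_of_room"
      next
    }
    d <- fr[fg] / 1000
    dc <- rbind(cam$focal_px, u_px[fg], v_px[fg])
    dwld <- t(cam$R) %*% dc
    dwld <- sweep(dwld, 2, sqrt(colSums(dwld^2)), "/")
    pts <- cam$position + sweep(dwld, 2, d, "*")
    # weight by depth^2: pixels subtend area proportional to d^2, correcting
    # the perspective density asymmetry of the projected blob
    w <- d^2
    ctr <- as.vector(pts %*% w) / sum(w)
    out$x_m[i] <- ctr[1]; out$y_m[i] <- ctr[2]; out$z_m[i] <- ctr[3]
  }
  out
}
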