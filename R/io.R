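# All tabular artifacts are CSV with fixed headers; numeric output uses full
# precision so write-then-read round-trips to 1e-9 and repeated runs are
# byte-identical.

TRAJ_HEADER <- c("time_s", "x_m", "y_m", "z_m", "activity")

#' Write / read a labeled trajectory CSV
#'
#' Dialect: header `time_s,x_m,y_m,z_m,activity`; coordinate fields are empty
#' exactly when activity is `out_of_room`.
#'
#' @param trajectory Trajectory data.frame.
#' @param path File path.
#' @return `write_trajectory`: the path, invisibly. `read_trajectory`: the
#'   trajectory data.frame.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(all(TRAJ_HEADER %in% names(trajectory)))
  data.table::fwrite(trajectory[, TRAJ_HEADER], path, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  hdr <- strsplit(readLines(path, n = 1), ",", fixed = TRUE)[[1]]
  if (!identical(hdr, TRAJ_HEADER))
    stopf("%s: malformed header: expected '%s', got '%s'", path,
          paste(TRAJ_HEADER, collapse = ","), paste(hdr, collapse = ","))
  dt <- data.table::fread(path, colClasses = list(
    numeric = c("time_s", "x_m", "y_m", "z_m"), character = "activity"),
    na.strings = "")
  df <- as.data.frame(dt)
  bad <- which(!is.na(df$activity) & !(df$activity %in% FW_ACTIVITIES))
  if (length(bad))
    stopf("%s: unknown activity token '%s' at line %d", path,
          df$activity[bad[1]], bad[1] + 1L)
  df
}

#' Write / read the per-subject feature table CSV
#'
#' Columns: `subject_id` plus the 15 canonical parameter names.
#'
#' @param features Feature data.frame.
#' @param path File path.
#' @export
write_features <- function(features, path) {
  stopifnot(all(c("subject_id", FW_PARAMS) %in% names(features)))
  data.table::fwrite(features[, c("subject_id", FW_PARAMS)], path, na = "NA",
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- as.data.frame(data.table::fread(path, na.strings = "NA"))
  miss <- setdiff(c("subject_id", FW_PARAMS), names(df))
  if (length(miss))
    stopf("%s: missing feature column(s): %s", path, paste(miss, collapse = ", "))
  df
}

#' Write / read the labels CSV (`subject_id,label,source`)
#'
#' @param labels Labels data.frame from [label_cohort()].
#' @param path File path.
#' @export
write_labels <- function(labels, path) {
  stopifnot(all(c("subject_id", "label", "source") %in% names(labels)))
  data.table::fwrite(labels[, c("subject_id", "label", "source")], path,
                     na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  df <- as.data.frame(data.table::fread(path, na.strings = "NA"))
  if (!identical(names(df), c("subject_id", "label", "source")))
    stopf("%s: malformed labels header", path)
  bad <- which(!is.na(df$label) & !(df$label %in% c("low", "high")))
  if (length(bad)) stopf("%s: unknown label '%s' at line %d", path,
                         df$label[bad[1]], bad[1] + 1L)
  df
}

#' Write / read benchmark results JSON
#'
#' Serializes every combination-by-algorithm evaluation (features, algorithm,
#' per-fold correctness, accuracy).
#'
#' @param benchmark An `fw_benchmark` (or list of `fw_eval`).
#' @param path File path.
#' @export
write_results_json <- function(benchmark, path) {
  results <- if (inherits(benchmark, "fw_benchmark")) benchmark$results
    else benchmark
  payload <- lapply(results, function(r) list(
    features = r$feature_names, algorithm = r$algorithm,
    per_fold_correct = unname(r$per_fold_correct),
    subjects = names(r$per_fold_correct),
    mean_accuracy = r$mean_accuracy, n_used = r$n_used))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' @rdname write_results_json
#' @export
read_results_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

#' Write / read a cohort JSON (clinical scores and groups)
#'
#' @param cohort An `fw_cohort`.
#' @param path File path.
#' @export
write_cohort_json <- function(cohort, path) {
  payload <- list(
    config = cohort$config[c("n_subjects", "n_low_risk", "frame_rate",
                             "day_duration", "separation_mode",
                             "n_incongruent", "noise_sd")],
    subjects = lapply(cohort$subjects, function(s)
      s[c("subject_id", "true_group", "tinetti_score", "tug_trials",
          "fell_before")]))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cohort_json
#' @export
read_cohort_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  x$subjects <- lapply(x$subjects, function(s) {
    s$tug_trials <- unlist(s$tug_trials)
    s
  })
  x
}

#' Write a per-subject ground-truth JSON
#'
#' @param truth The `truth` element of a [simulate_day()] result.
#' @param path File path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(list(
    steps = truth$steps, transitions = truth$transitions,
    totals = as.list(truth$totals)), path, auto_unbox = TRUE, digits = NA,
    dataframe = "columns")
  invisible(path)
}

#' Write / read a depth sequence directory
#'
#' Plain-text layout: `camera.json`, `background.csv`, `timestamps.csv` and
#' one integer-mm `frame_NNNN.csv` per frame (text-only stand-in for 16-bit
#' depth PNGs).
#'
#' @param depth An `fw_depth_sequence`.
#' @param dir Output directory (created).
#' @export
write_depth_sequence <- function(depth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cam <- depth$camera
  jsonlite::write_json(cam[c("position", "tilt_deg", "image_size", "focal_px",
                             "depth_range_mm", "room")],
                       file.path(dir, "camera.json"), auto_unbox = FALSE,
                       digits = NA)
  data.table::fwrite(as.data.frame(depth$background),
                     file.path(dir, "background.csv"), col.names = FALSE)
  data.table::fwrite(data.frame(time_s = depth$timestamps),
                     file.path(dir, "timestamps.csv"))
  for (i in seq_along(depth$frames))
    data.table::fwrite(as.data.frame(depth$frames[[i]]),
                       file.path(dir, sprintf("frame_%04d.csv", i)),
                       col.names = FALSE)
  invisible(dir)
}

#' @rdname write_depth_sequence
#' @export
read_depth_sequence <- function(dir) {
  camj <- jsonlite::read_json(file.path(dir, "camera.json"),
                              simplifyVector = TRUE)
  cam <- camera_model(position = camj$position, tilt_deg = camj$tilt_deg,
                      image_size = camj$image_size, focal_px = camj$focal_px,
                      depth_range_mm = camj$depth_range_mm, room = camj$room)
  bg <- as.matrix(data.table::fread(file.path(dir, "background.csv"),
                                    header = FALSE))
  dimnames(bg) <- NULL
  ts <- as.data.frame(data.table::fread(file.path(dir, "timestamps.csv")))$time_s
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.csv$",
                           full.names = TRUE))
  frames <- lapply(files, function(f) {
    m <- as.matrix(data.table::fread(f, header = FALSE))
    dimnames(m) <- NULL
    m
  })
  structure(list(frames = frames, timestamps = ts, camera = cam,
                 background = bg), class = "fw_depth_sequence")
}

#' Read a pipeline configuration YAML
#'
#' Mirrors [cohort_config()] plus pipeline stage settings (`algorithms`,
#' `max_combo`, `n_boot`). Unknown keys error; required keys must be present.
#'
#' @param path YAML file path.
#' @return Validated named list.
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  required <- c("n_subjects", "n_low_risk", "day_duration")
  known <- c(required, "frame_rate", "separation_mode", "n_incongruent",
             "noise_sd", "algorithms", "max_combo", "n_boot", "parameters")
  for (k in required) if (is.null(raw[[k]]))
    stopf("config %s: missing required key '%s'", path, k)
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stopf("config %s: unknown key(s): %s", path, paste(unknown, collapse = ", "))
  raw
}
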