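# Canonical order of the 15 behavioral parameters. Every feature table, stats
# table and combination enumeration uses exactly these names.
FW_PARAMS <- c(
  "total_lying_pct", "total_sitting_pct", "out_of_room_pct", "n_transitions",
  "time_to_sit_s", "speed_to_sit_mps", "time_to_get_up_s", "speed_to_get_up_mps",
  "mean_step_length_m", "cv_step_length", "mean_step_duration_s",
  "cv_step_duration", "mean_pace_steps_per_s", "cv_pace", "mean_gait_speed_mps"
)

FW_ACTIVITIES <- c("walking", "standing", "sitting", "lying", "out_of_room")

#' Parameter names of the behavioral feature set
#'
#' Canonical names (and order) of the fifteen per-subject behavioral
#' parameters produced by [extract_parameters()].
#'
#' @return Character vector of length 15.
#' @export
parameter_names <- function() FW_PARAMS

# Run `expr` under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic per-stage / per-unit seed derivation from one master seed,
# kept strictly below 2^31 (R integers are 32-bit).
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(offset)) %% 2147483647)
}

# sample sd / mean; NA when fewer than 2 values
coef_var <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2 || mean(x) == 0) return(NA_real_)
  stats::sd(x) / mean(x)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
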