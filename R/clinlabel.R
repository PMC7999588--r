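#' Labeling configuration
#'
#' Cutoffs and resolution rule for the reference clinical fall-risk label.
#' Defaults: Tinetti scores below 21 are high risk; best-of-three TUG times of
#' 13.5 s or more are high risk; disagreements resolve to high risk
#' ("assume the person is at risk when there is a doubt").
#'
#' @param tinetti_cutoff Tinetti threshold (high iff score < cutoff).
#' @param tug_cutoff TUG threshold in seconds (high iff best trial >= cutoff).
#' @param resolution Resolution rule identifier; only `"high_wins"` is defined.
#' @param use_fall_history If TRUE, a recorded previous fall also forces the
#'   resolved label to high risk (optional override, default off).
#' @return List of class `fw_label_config`.
#' @export
labeling_config <- function(tinetti_cutoff = 21, tug_cutoff = 13.5,
                            resolution = "high_wins",
                            use_fall_history = FALSE) {
  if (tinetti_cutoff <= 0 || tug_cutoff <= 0)
    stopf("cutoffs must be > 0")
  structure(list(tinetti_cutoff = tinetti_cutoff, tug_cutoff = tug_cutoff,
                 resolution = resolution, use_fall_history = use_fall_history),
            class = "fw_label_config")
}

risk_label <- function(value, source) {
  structure(list(value = value, source = source), class = "fw_risk_label")
}

#' Fall-risk label from a Tinetti score
#'
#' High risk iff the score is strictly below the cutoff (default 21; 21 itself
#' is low/no risk, 28 is the scale maximum meaning no risk).
#'
#' @param score Integer Tinetti score in 0..28.
#' @param config A [labeling_config()].
#' @return `fw_risk_label`: list with `value` ("low"/"high") and `source`.
#' @export
tinetti_label <- function(score, config = labeling_config()) {
  if (!is.finite(score) || score < 0 || score > 28)
    stopf("tinetti score out of range [0, 28]: %s", format(score))
  risk_label(if (score < config$tinetti_cutoff) "high" else "low", "tinetti")
}

#' Fall-risk label from TUG trials
#'
#' The fastest of up to three trials is used; high risk iff that best time is
#' greater than or equal to the cutoff (default 13.5 s).
#'
#' @param trials Numeric vector of 1-3 positive trial times, seconds.
#' @param config A [labeling_config()].
#' @return `fw_risk_label`.
#' @export
tug_label <- function(trials, config = labeling_config()) {
  if (length(trials) < 1 || length(trials) > 3 || any(!is.finite(trials)) ||
      any(trials <= 0))
    stopf("TUG trials must be 1-3 positive times")
  risk_label(if (min(trials) >= config$tug_cutoff) "high" else "low", "tug")
}

#' Resolve two clinical labels into the reference label
#'
#' High risk iff either test says high; `source` is `"resolved"` when the two
#' disagree, otherwise the (agreeing) tests' common verdict keeps a test
#' source for audit.
#'
#' @param tinetti,tug `fw_risk_label` objects.
#' @return `fw_risk_label`.
#' @export
resolve_labels <- function(tinetti, tug) {
  if (tinetti$value == tug$value)
    return(risk_label(tinetti$value, "tinetti"))
  risk_label("high", "resolved")
}

#' Label a whole cohort from its clinical scores
#'
#' @param cohort An `fw_cohort`, or a list of profiles with `subject_id`,
#'   `tinetti_score`, `tug_trials` (and optionally `fell_before`).
#' @param config A [labeling_config()].
#' @return data.frame `subject_id, label, source`; missing scores yield `NA`.
#' @export
label_cohort <- function(cohort, config = labeling_config()) {
  subs <- if (inherits(cohort, "fw_cohort")) cohort$subjects else cohort
  rows <- lapply(subs, function(s) {
    if (is.null(s$tinetti_score) || is.null(s$tug_trials) ||
        any(is.na(s$tinetti_score)) || any(is.na(s$tug_trials)))
      return(data.frame(subject_id = s$subject_id, label = NA_character_,
                        source = NA_character_, stringsAsFactors = FALSE))
    lab <- resolve_labels(tinetti_label(s$tinetti_score, config),
                          tug_label(s$tug_trials, config))
    if (config$use_fall_history && isTRUE(s$fell_before) &&
        lab$value == "low")
      lab <- risk_label("high", "resolved")
    data.frame(subject_id = s$subject_id, label = lab$value,
               source = lab$source, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cutoff-robustness sweep
#'
#' Checks whether any cutoff inside a stated interval changes the labeling of
#' a cohort — the checkable analog of reporting that a TUG threshold anywhere
#' between 13 and 16.4 s leaves the classification unchanged.
#'
#' @param cohort Cohort or profile list (see [label_cohort()]).
#' @param which `"tug"` or `"tinetti"`: which cutoff to sweep.
#' @param interval Numeric `c(lo, hi)` sweep interval.
#' @param step Sweep step size.
#' @param config Base [labeling_config()].
#' @return List: `stable` (logical), `cutoffs` tried, and `n_changed` per
#'   cutoff relative to the base configuration.
#' @export
sweep_cutoff <- function(cohort, which = c("tug", "tinetti"),
                         interval, step = 0.1, config = labeling_config()) {
  which <- match.arg(which)
  base <- label_cohort(cohort, config)$label
  cutoffs <- seq(interval[1], interval[2], by = step)
  n_changed <- vapply(cutoffs, function(cut) {
    cfg <- config
    if (which == "tug") cfg$tug_cutoff <- cut else cfg$tinetti_cutoff <- cut
    sum(label_cohort(cohort, cfg)$label != base, na.rm = TRUE)
  }, 0)
  list(stable = all(n_changed == 0), cutoffs = cutoffs, n_changed = n_changed)
}
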