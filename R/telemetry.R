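#' Trial recording: one surgeon performing one exercise
#'
#' Bundles a kinematic sample stream, a discrete event stream, and trial
#' metadata into a validated `trial_recording` object. Kinematics hold 3-D
#' positions (meters) of the two hand controllers, the endoscope, and one or
#' more instrument tips, sampled on a strictly increasing time base (seconds
#' from trial start).
#'
#' @param surgeon_id Opaque surgeon identifier (single string).
#' @param group Experience group, one of [experience_groups()].
#' @param exercise_id Exercise name (single string).
#' @param sample_rate Nominal sampling rate in Hz (positive scalar).
#' @param samples Tibble/data frame of kinematic samples with columns
#'   `t, lx, ly, lz, rx, ry, rz, ex, ey, ez` and one `i<k>x, i<k>y, i<k>z`
#'   triplet per instrument (k = 1..N, N >= 1). Units are meters; `t` is in
#'   seconds, non-negative and strictly increasing; at least two samples.
#' @param events Tibble/data frame with columns `t` (seconds, within the trial
#'   span) and `kind` (one of [event_kinds()]). May have zero rows.
#' @param overall_score Optional dimensionless composite score (scalar), or
#'   `NULL` when not available.
#'
#' @return An object of class `trial_recording`: a list with the validated
#'   fields above plus no others. Its duration (last minus first sample time)
#'   is strictly positive.
#' @export
#' @examples
#' tr <- trial_recording(
#'   surgeon_id = "S01", group = "new", exercise_id = "Pick and Place",
#'   sample_rate = 50,
#'   samples = tibble::tibble(
#'     t = c(0, 0.02, 0.04),
#'     lx = 0, ly = 0, lz = 0, rx = 0.1, ry = 0, rz = 0,
#'     ex = 0, ey = 0, ez = 0.1, i1x = 0, i1y = 0, i1z = 0
#'   )
#' )
#' completion_time(tr)
trial_recording <- function(surgeon_id, group, exercise_id, sample_rate,
                            samples, events = empty_events(),
                            overall_score = NULL) {
  if (!is.character(surgeon_id) || length(surgeon_id) != 1L || !nzchar(surgeon_id)) {
    stop_validation("`surgeon_id` must be a non-empty string")
  }
  if (!is.character(group) || length(group) != 1L || !group %in% experience_groups()) {
    stop_validation(sprintf(
      "`group` must be one of: %s", paste(experience_groups(), collapse = ", ")
    ))
  }
  if (!is.character(exercise_id) || length(exercise_id) != 1L || !nzchar(exercise_id)) {
    stop_validation("`exercise_id` must be a non-empty string")
  }
  if (!is_scalar_number(sample_rate) || sample_rate <= 0) {
    stop_validation("`sample_rate` must be a single positive number (Hz)")
  }
  samples <- validate_samples(samples)
  duration <- samples$t[nrow(samples)] - samples$t[1L]
  if (!(duration > 0)) stop_validation("trial duration must be > 0")
  events <- validate_events(events, duration)
  if (!is.null(overall_score) && !is_scalar_number(overall_score)) {
    stop_validation("`overall_score` must be NULL or a single finite number")
  }

  structure(
    list(
      surgeon_id = surgeon_id, group = group, exercise_id = exercise_id,
      sample_rate = sample_rate, samples = samples, events = events,
      overall_score = overall_score
    ),
    class = "trial_recording"
  )
}

#' @export
print.trial_recording <- function(x, ...) {
  score <- if (is.null(x$overall_score)) "none" else format(x$overall_score)
  cat(sprintf(
    paste0(
      "<trial_recording> surgeon %s (%s), exercise \"%s\"\n",
      "  %d samples @ %g Hz over %.2f s, %d instrument(s), %d event(s), score: %s\n"
    ),
    x$surgeon_id, x$group, x$exercise_id,
    nrow(x$samples), x$sample_rate,
    x$samples$t[nrow(x$samples)] - x$samples$t[1L],
    n_instruments(x), nrow(x$events), score
  ))
  invisible(x)
}

#' Number of instrument-tip streams in a trial
#'
#' @param trial A [trial_recording()].
#' @return Integer count of `i<k>x/y/z` column triplets (>= 1).
#' @export
n_instruments <- function(trial) {
  length(grep("^i[0-9]+x$", names(trial$samples)))
}

empty_events <- function() {
  tibble::tibble(t = numeric(0), kind = character(0))
}

fixed_kin_cols <- c("t", "lx", "ly", "lz", "rx", "ry", "rz", "ex", "ey", "ez")

kin_col_names <- function(n_instruments) {
  inst <- as.vector(t(outer(seq_len(n_instruments),
                            c("x", "y", "z"),
                            function(k, ax) paste0("i", k, ax))))
  c(fixed_kin_cols, inst)
}

validate_samples <- function(samples) {
  samples <- tibble::as_tibble(samples)
  missing_fixed <- setdiff(fixed_kin_cols, names(samples))
  if (length(missing_fixed)) {
    stop_validation(sprintf(
      "kinematics missing required column(s): %s",
      paste(missing_fixed, collapse = ", ")
    ))
  }
  n_inst <- length(grep("^i[0-9]+x$", names(samples)))
  if (n_inst < 1L) {
    stop_validation("kinematics must contain at least one instrument triplet (i1x, i1y, i1z)")
  }
  expected <- kin_col_names(n_inst)
  extra <- setdiff(names(samples), expected)
  if (length(extra)) {
    stop_validation(sprintf(
      "unrecognised kinematics column(s): %s", paste(extra, collapse = ", ")
    ))
  }
  missing_inst <- setdiff(expected, names(samples))
  if (length(missing_inst)) {
    stop_validation(sprintf(
      "incomplete instrument triplet; missing: %s", paste(missing_inst, collapse = ", ")
    ))
  }
  samples <- samples[, expected]
  if (nrow(samples) < 2L) stop_validation("kinematics must contain at least 2 samples")
  for (col in expected) {
    bad <- which(!is.finite(samples[[col]]))
    if (length(bad)) {
      stop_validation(sprintf(
        "non-finite value in kinematics column `%s` at row %d", col, bad[1L]
      ))
    }
  }
  if (samples$t[1L] < 0) stop_validation("timestamps must be >= 0 (row 1)")
  nonmono <- which(diff(samples$t) <= 0)
  if (length(nonmono)) {
    stop_validation(sprintf(
      "timestamps must be strictly increasing; first violation at row %d",
      nonmono[1L] + 1L
    ))
  }
  samples
}

validate_events <- function(events, duration) {
  events <- tibble::as_tibble(events)
  if (!all(c("t", "kind") %in% names(events))) {
    stop_validation("events must have columns `t` and `kind`")
  }
  events <- events[, c("t", "kind")]
  if (nrow(events) == 0L) {
    return(tibble::tibble(t = numeric(0), kind = character(0)))
  }
  if (!is.numeric(events$t) || any(!is.finite(events$t))) {
    stop_validation("event times must be finite numbers")
  }
  bad_kind <- setdiff(unique(events$kind), event_kinds())
  if (length(bad_kind)) {
    stop_validation(sprintf(
      "unknown event kind(s): %s (allowed: %s)",
      paste(bad_kind, collapse = ", "), paste(event_kinds(), collapse = ", ")
    ))
  }
  out_of_span <- which(events$t < 0 | events$t > duration)
  if (length(out_of_span)) {
    stop_validation(sprintf(
      "event time outside [0, duration] at row %d", out_of_span[1L]
    ))
  }
  events[order(events$t), ]
}
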