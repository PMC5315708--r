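#' Camera movement frequency (CFrq)
#'
#' Average number of endoscope movements per second over the whole exercise:
#' `count(episodes) / comp_time`.
#'
#' @param episodes Episode tibble (`start`, `end`).
#' @param comp_time Completion time in seconds (> 0).
#' @return Movements per second (>= 0).
#' @export
camera_movement_frequency <- function(episodes, comp_time) {
  if (!is_scalar_number(comp_time) || comp_time <= 0) {
    stop_domain("`comp_time` must be > 0")
  }
  nrow(episodes) / comp_time
}

#' Camera movement duration (CDur)
#'
#' Mean length, in seconds, of the endoscope movements in an exercise.
#' `NA` when there are no episodes: a trial without camera movements has no
#' movement duration (coding it 0 would fake instantaneous movements and
#' bias group means downward).
#'
#' @param episodes Episode tibble (`start`, `end`).
#' @return Mean episode duration in seconds, or `NA_real_` if no episodes.
#' @export
camera_movement_duration <- function(episodes) {
  if (nrow(episodes) == 0L) return(NA_real_)
  mean(episodes$end - episodes$start)
}

#' Camera movement interval (CInt)
#'
#' Mean time, in seconds, between endoscope movements. With the default
#' `"gap"` convention this is the mean of the idle gaps
#' `start[i+1] - end[i]` between consecutive episodes, i.e. time during which
#' the viewpoint is held; `"start_to_start"` measures the movement period
#' instead (which double-counts durations already captured by CDur, but is
#' offered for sensitivity analysis). `NA` with fewer than two episodes.
#'
#' @param episodes Episode tibble (`start`, `end`).
#' @param convention `"gap"` (default) or `"start_to_start"`.
#' @return Mean interval in seconds, or `NA_real_` with < 2 episodes.
#' @export
camera_movement_interval <- function(episodes,
                                     convention = c("gap", "start_to_start")) {
  convention <- match.arg(convention)
  n <- nrow(episodes)
  if (n < 2L) return(NA_real_)
  if (convention == "gap") {
    mean(episodes$start[-1L] - episodes$end[-n])
  } else {
    mean(diff(episodes$start))
  }
}

#' Completion time (CompTime)
#'
#' Total time in seconds to complete an exercise: the time of the last
#' kinematic sample minus the time of the first.
#'
#' @param trial A [trial_recording()].
#' @return Completion time in seconds (> 0).
#' @export
completion_time <- function(trial) {
  t <- trial$samples$t
  if (length(t) < 2L) stop_domain("completion time needs at least 2 samples")
  t[length(t)] - t[1L]
}

#' Economy of motion (EOM)
#'
#' Total 3-D distance travelled by the instrument tips over an exercise, in
#' meters: the Euclidean polyline length of each instrument-tip trajectory,
#' summed across all instruments present in the stream.
#'
#' @param trial A [trial_recording()].
#' @return Path length in meters (>= 0).
#' @export
economy_of_motion <- function(trial) {
  s <- trial$samples
  if (nrow(s) < 2L) stop_domain("economy of motion needs at least 2 samples")
  total <- 0
  for (k in seq_len(n_instruments(trial))) {
    mat <- cbind(s[[paste0("i", k, "x")]], s[[paste0("i", k, "y")]],
                 s[[paste0("i", k, "z")]])
    steps <- diff(mat)
    total <- total + sum(sqrt(rowSums(steps^2)))
  }
  total
}

#' Master workspace range (MWR)
#'
#' Radius, in meters, summarising how far the hand controllers stray from
#' their average position. For each hand the centroid of its sampled 3-D
#' positions is taken and distances from that centroid computed. With
#' `mode = "scaled_max"` (default, the literal reading of "85% of the larger
#' of two radii"), the result is `0.85 * max(r_left, r_right)` where `r_h` is
#' the maximum distance for hand `h`. With `mode = "percentile"` (the reading
#' of 85% as a sample-coverage radius), `r_h` is the 85th percentile of the
#' distances and the result is `max(r_left, r_right)` unscaled.
#'
#' @param trial A [trial_recording()].
#' @param mode `"scaled_max"` (default) or `"percentile"`.
#' @return Workspace radius in meters (>= 0).
#' @export
master_workspace_range <- function(trial, mode = c("scaled_max", "percentile")) {
  mode <- match.arg(mode)
  s <- trial$samples
  radius <- function(prefix) {
    mat <- cbind(s[[paste0(prefix, "x")]], s[[paste0(prefix, "y")]],
                 s[[paste0(prefix, "z")]])
    centroid <- colMeans(mat)
    d <- sqrt(rowSums(sweep(mat, 2L, centroid)^2))
    if (mode == "scaled_max") max(d) else unname(quantile(d, 0.85))
  }
  r <- max(radius("l"), radius("r"))
  if (mode == "scaled_max") 0.85 * r else r
}

#' Compute the full per-trial metric set
#'
#' Assembles the three camera metrics (CFrq, CDur, CInt) and the conventional
#' kinematic metrics (CompTime, EOM, MWR) for one trial, passing through any
#' overall score in the metadata. When `episodes` is `NULL` they are derived
#' from the trial's camera events via [episodes_from_events()].
#'
#' @param trial A [trial_recording()].
#' @param episodes Optional episode tibble derived from the same trial.
#' @param mwr_mode Passed to [master_workspace_range()].
#' @param cint_convention Passed to [camera_movement_interval()].
#' @return One-row tibble with columns `surgeon_id`, `group`, `exercise_id`,
#'   `cfrq`, `cdur`, `cint`, `comp_time`, `eom`, `mwr`, `overall_score`,
#'   `n_episodes`. Missing CDur/CInt are `NA`. Satisfies
#'   `cfrq == n_episodes / comp_time`.
#' @export
compute_metric_set <- function(trial, episodes = NULL,
                               mwr_mode = c("scaled_max", "percentile"),
                               cint_convention = c("gap", "start_to_start")) {
  mwr_mode <- match.arg(mwr_mode)
  cint_convention <- match.arg(cint_convention)
  comp_time <- completion_time(trial)
  if (is.null(episodes)) {
    episodes <- episodes_from_events(trial$events, comp_time)
  }
  validate_episodes(episodes)
  tibble::tibble(
    surgeon_id = trial$surgeon_id,
    group = trial$group,
    exercise_id = trial$exercise_id,
    cfrq = camera_movement_frequency(episodes, comp_time),
    cdur = camera_movement_duration(episodes),
    cint = camera_movement_interval(episodes, cint_convention),
    comp_time = comp_time,
    eom = economy_of_motion(trial),
    mwr = master_workspace_range(trial, mwr_mode),
    overall_score = trial$overall_score %||% NA_real_,
    n_episodes = nrow(episodes)
  )
}

#' Metric table for a collection of trials
#'
#' Applies [compute_metric_set()] to each trial and binds the rows. Accepts
#' trials in memory or a cohort directory layout `dir/<surgeon>/<exercise>/`
#' as written by [write_cohort()].
#'
#' @param trials A list of [trial_recording()] objects, or a directory path.
#' @param use_kinematics If `TRUE`, episodes come from
#'   [episodes_from_kinematics()] instead of event markers.
#' @param seg_config [segmentation_config()] for the kinematic path.
#' @inheritParams compute_metric_set
#' @return Tibble with one metric row per trial.
#' @export
cohort_metrics <- function(trials, use_kinematics = FALSE,
                           seg_config = segmentation_config(),
                           mwr_mode = c("scaled_max", "percentile"),
                           cint_convention = c("gap", "start_to_start")) {
  mwr_mode <- match.arg(mwr_mode)
  cint_convention <- match.arg(cint_convention)
  if (is.character(trials)) {
    paths <- list.dirs(trials, recursive = TRUE, full.names = TRUE)
    paths <- paths[file.exists(file.path(paths, "meta.json"))]
    trials <- lapply(paths, read_trial)
  }
  rows <- lapply(trials, function(tr) {
    ep <- if (use_kinematics) {
      episodes_from_kinematics(tr$samples, seg_config)
    } else {
      NULL
    }
    compute_metric_set(tr, episodes = ep, mwr_mode = mwr_mode,
                       cint_convention = cint_convention)
  })
  dplyr::bind_rows(rows)
}
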