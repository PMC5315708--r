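#' Group profile for the synthetic cohort generator
#'
#' Parameters of one experience group on one exercise. Camera behaviour is an
#' alternating renewal process: Gamma-distributed viewpoint-hold gaps (mean
#' `target_cint`, shape `gap_shape`) alternate with Gamma-distributed camera
#' movements (mean `target_cdur`, shape `dur_shape`), so frequency, duration
#' and interval are independently tunable and the long-run movement rate is
#' `1 / (target_cint + target_cdur)`. Trial completion times are lognormal
#' (strictly positive, right-skewed, as observed for novice surgeons).
#' Between-surgeon heterogeneity enters as per-trial lognormal multipliers on
#' the pacing (gap) and duration scales with coefficients of variation
#' `pace_cv` and `dur_cv`; these are what give group-level standard
#' deviations a realistic size relative to the means.
#'
#' @param group Group label, one of [experience_groups()].
#' @param mean_comp_time Mean completion time, seconds.
#' @param cv_comp_time Coefficient of variation of completion time.
#' @param target_cint Mean viewpoint-hold gap between camera movements, s.
#' @param target_cdur Mean camera movement duration, s.
#' @param gap_shape,dur_shape Gamma shape parameters (default 2: mild right
#'   skew, standard deviation about 70% of the mean).
#' @param path_speed Expected instrument-tip speed, m/s.
#' @param hand_sigma Per-axis standard deviation of hand-controller positions
#'   about their centroid, m.
#' @param endo_speed Endoscope speed during camera movements, m/s.
#' @param pace_cv,dur_cv Between-trial lognormal CVs on the gap and duration
#'   scales (0 disables heterogeneity).
#' @param n_instruments Number of instrument-tip streams to simulate.
#' @return A `group_profile` list.
#' @export
group_profile <- function(group, mean_comp_time, cv_comp_time,
                          target_cint, target_cdur,
                          gap_shape = 2, dur_shape = 2,
                          path_speed = 0.01, hand_sigma = 0.04,
                          endo_speed = 0.012,
                          pace_cv = 0, dur_cv = 0,
                          n_instruments = 2L) {
  if (!group %in% experience_groups()) {
    stop_config(sprintf("`group` must be one of: %s",
                        paste(experience_groups(), collapse = ", ")))
  }
  for (nm in c("mean_comp_time", "cv_comp_time", "target_cint", "target_cdur",
               "gap_shape", "dur_shape", "path_speed", "hand_sigma")) {
    assert_positive_scalar(get(nm), nm)
  }
  if (!is_scalar_number(endo_speed) || endo_speed < 0) {
    stop_config("`endo_speed` must be a single non-negative number")
  }
  if (!is_scalar_number(pace_cv) || pace_cv < 0 ||
      !is_scalar_number(dur_cv) || dur_cv < 0) {
    stop_config("`pace_cv` and `dur_cv` must be non-negative numbers")
  }
  if (!is_scalar_number(n_instruments) || n_instruments < 1) {
    stop_config("`n_instruments` must be >= 1")
  }
  if (!(target_cint + target_cdur <= mean_comp_time)) {
    stop_config("target_cint + target_cdur must not exceed mean_comp_time")
  }
  structure(
    list(group = group, mean_comp_time = mean_comp_time,
         cv_comp_time = cv_comp_time, target_cint = target_cint,
         target_cdur = target_cdur, gap_shape = gap_shape,
         dur_shape = dur_shape, path_speed = path_speed,
         hand_sigma = hand_sigma, endo_speed = endo_speed,
         pace_cv = pace_cv, dur_cv = dur_cv,
         n_instruments = as.integer(n_instruments)),
    class = "group_profile"
  )
}

#' Default group profiles
#'
#' Baseline (difficulty 1) profiles calibrated so camera-metric group means
#' and standard deviations sit at the scales reported for da Vinci Skills
#' Simulator cohorts: new surgeons around 0.04 camera movements/s with long
#' (~1.4 s) movements and long (~24 s) holds; experienced surgeons around
#' 0.14 movements/s with short (~0.8 s) movements and short (~6.4 s) holds;
#' intermediates in between, close to experienced. Completion times shrink
#' and instrument speed rises with experience; hand workspace shrinks only
#' slightly, so workspace range discriminates weakly (as it does in
#' practice). The `difficulty` multiplier scales pacing, movement duration,
#' and completion time to emulate exercises of different demands.
#'
#' @param difficulty Positive scalar difficulty multiplier for one exercise.
#' @return Named list of three [group_profile()]s
#'   (`new`, `intermediate`, `experienced`).
#' @export
default_profiles <- function(difficulty = 1) {
  assert_positive_scalar(difficulty, "difficulty")
  d <- difficulty
  ws <- 0.7 + 0.5 * (d - 0.6) # workspace varies by exercise more than by group
  list(
    new = group_profile(
      "new", mean_comp_time = 240 * d, cv_comp_time = 0.35,
      target_cint = 23.6 * d, target_cdur = 1.4 * (0.7 + 0.3 * d),
      path_speed = 0.008 * d, hand_sigma = 0.045 * ws, endo_speed = 0.010,
      pace_cv = 0.75, dur_cv = 0.30
    ),
    intermediate = group_profile(
      "intermediate", mean_comp_time = 170 * d, cv_comp_time = 0.30,
      target_cint = 8.1 * d, target_cdur = 0.95 * (0.7 + 0.3 * d),
      path_speed = 0.010 * d, hand_sigma = 0.042 * ws, endo_speed = 0.012,
      pace_cv = 0.45, dur_cv = 0.25
    ),
    experienced = group_profile(
      "experienced", mean_comp_time = 140 * d, cv_comp_time = 0.25,
      target_cint = 6.4 * d, target_cdur = 0.80 * (0.7 + 0.3 * d),
      path_speed = 0.011 * d, hand_sigma = 0.040 * ws, endo_speed = 0.013,
      pace_cv = 0.35, dur_cv = 0.25
    )
  )
}

#' The 25 standard da Vinci Skills Simulator exercise names
#'
#' @return Character vector of 25 exercise names.
#' @export
dvss_exercises <- function() {
  c("Camera Targeting-Level 1", "Camera Targeting-Level 2",
    "Dots and Needles-Level 1", "Dots and Needles-Level 2",
    "Energy Dissection-Level 1", "Energy Dissection-Level 2",
    "Energy Switching-Level 1", "Match Board-Level 1", "Match Board-Level 2",
    "Match Board-Level 3", "Needle Targeting", "Peg Board-Level 1",
    "Peg Board-Level 2", "Pick and Place", "Ring and Rail-Level 1",
    "Ring and Rail-Level 2", "Ring Walk-Level 1", "Ring Walk-Level 2",
    "Ring Walk-Level 3", "Scaling", "Suture Sponge-Level 1",
    "Suture Sponge-Level 2", "Suture Sponge-Level 3", "Thread the Rings",
    "Tubes")
}

#' Cohort specification
#'
#' Defines a synthetic cohort: which exercises, how many surgeons per
#' experience group (default 18 new / 8 intermediate / 13 experienced), the
#' kinematic sampling rate, the generating profiles, and a mandatory seed.
#'
#' @param exercises Character vector of exercise ids (no duplicates).
#' @param seed Integer seed driving all randomness (mandatory).
#' @param group_sizes Named integer vector with entries `new`,
#'   `intermediate`, `experienced`; each >= 2.
#' @param sample_rate Sampling rate in Hz.
#' @param profiles Either `NULL` (defaults built from `difficulty`), or a
#'   named list `profiles[[exercise]][[group]]` of [group_profile()]s.
#' @param difficulty Numeric vector of per-exercise difficulty multipliers
#'   (recycled/defaulted to an even spread over `[0.6, 1.6]`), used only when
#'   `profiles` is `NULL`.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(exercises, seed,
                        group_sizes = c(new = 18L, intermediate = 8L, experienced = 13L),
                        sample_rate = 50,
                        profiles = NULL, difficulty = NULL) {
  if (missing(seed) || !is_scalar_number(seed) || seed != round(seed)) {
    stop_config("`seed` is mandatory and must be a single integer")
  }
  if (!is.character(exercises) || length(exercises) < 1L) {
    stop_config("`exercises` must be a non-empty character vector")
  }
  if (anyDuplicated(exercises)) stop_config("duplicate exercise ids")
  if (!all(experience_groups() %in% names(group_sizes))) {
    stop_config("`group_sizes` must name new, intermediate and experienced")
  }
  group_sizes <- group_sizes[experience_groups()]
  if (any(group_sizes < 2)) {
    stop_config("each group entering a t-test needs size >= 2")
  }
  assert_positive_scalar(sample_rate, "sample_rate")

  if (is.null(profiles)) {
    n_ex <- length(exercises)
    if (is.null(difficulty)) {
      difficulty <- if (n_ex == 1L) 1 else seq(0.6, 1.6, length.out = n_ex)
    }
    difficulty <- rep_len(difficulty, n_ex)
    profiles <- lapply(difficulty, default_profiles)
    names(profiles) <- exercises
  } else {
    if (!all(exercises %in% names(profiles))) {
      stop_config("`profiles` must contain an entry for every exercise")
    }
    for (ex in exercises) {
      if (!all(experience_groups() %in% names(profiles[[ex]]))) {
        stop_config(sprintf("profiles for exercise \"%s\" must cover all groups", ex))
      }
    }
  }

  structure(
    list(exercises = exercises, group_sizes = group_sizes,
         sample_rate = sample_rate, seed = as.integer(seed),
         profiles = profiles),
    class = "cohort_spec"
  )
}

#' Default cohort specification
#'
#' The standard study layout: the 25 simulator exercises, 18/8/13 surgeons
#' per group, 50 Hz kinematics, default calibrated profiles.
#'
#' @param seed Integer seed.
#' @param exercises Exercise names (default [dvss_exercises()]).
#' @param sample_rate Sampling rate, Hz.
#' @inheritParams cohort_spec
#' @return A [cohort_spec()].
#' @export
default_cohort_spec <- function(seed, exercises = dvss_exercises(),
                                sample_rate = 50,
                                group_sizes = c(new = 18L, intermediate = 8L,
                                                experienced = 13L)) {
  cohort_spec(exercises = exercises, seed = seed, group_sizes = group_sizes,
              sample_rate = sample_rate)
}

#' Generate one synthetic trial
#'
#' Draws a completion time, lays down camera episodes from the alternating
#' renewal process (episodes that would run past the end of the trial are
#' dropped: a trial ends with instruments, not mid-camera-move), and
#' synthesises kinematics: the endoscope integrates `endo_speed` along a
#' random constant heading within each episode and is stationary outside;
#' instrument tips move at `path_speed` along a smoothly wandering heading;
#' hand-controller positions are i.i.d. Gaussian about fixed centroids.
#' `camera_start`/`camera_stop` events are emitted at episode boundaries and
#' a `head_in` event at t = 0. All randomness derives from `seed`.
#'
#' @param profile A [group_profile()].
#' @param surgeon_id,exercise_id Identifiers for the trial.
#' @param sample_rate Sampling rate, Hz.
#' @param seed Integer seed for this trial.
#' @return A [trial_recording()].
#' @export
generate_trial <- function(profile, surgeon_id, exercise_id,
                           sample_rate = 50, seed) {
  stopifnot(inherits(profile, "group_profile"))
  if (missing(seed) || !is_scalar_number(seed)) {
    stop_config("`seed` is mandatory for generate_trial()")
  }
  withr::with_seed(as.integer(seed), {
    comp_time <- rlnorm_mean_cv(1L, profile$mean_comp_time, profile$cv_comp_time)
    comp_time <- max(comp_time, 20 / sample_rate) # keep degenerate draws viable

    pace_mult <- lnorm_mult(profile$pace_cv)
    dur_mult <- lnorm_mult(profile$dur_cv)
    cint_i <- profile$target_cint * pace_mult
    cdur_i <- profile$target_cdur * dur_mult

    ep <- draw_episodes(comp_time, cint_i, cdur_i,
                        profile$gap_shape, profile$dur_shape)

    # sample grid: regular steps plus the exact endpoint so the trial span
    # equals the drawn completion time
    dt <- 1 / sample_rate
    t <- seq(0, comp_time, by = dt)
    if (t[length(t)] < comp_time) t <- c(t, comp_time)
    n <- length(t)

    endo <- endoscope_track(t, ep, profile$endo_speed)
    inst <- lapply(seq_len(profile$n_instruments), function(k) {
      instrument_track(t, profile$path_speed, sample_rate,
                       origin = c(0, 0.02 * k, 0.05))
    })
    lh <- hand_track(n, profile$hand_sigma, c(-0.10, 0, 0))
    rh <- hand_track(n, profile$hand_sigma, c(0.10, 0, 0))

    cols <- c(
      list(t = t,
           lx = lh[, 1L], ly = lh[, 2L], lz = lh[, 3L],
           rx = rh[, 1L], ry = rh[, 2L], rz = rh[, 3L],
           ex = endo[, 1L], ey = endo[, 2L], ez = endo[, 3L]),
      stats::setNames(
        unlist(lapply(inst, function(m) list(m[, 1L], m[, 2L], m[, 3L])),
               recursive = FALSE),
        as.vector(t(outer(seq_along(inst), c("x", "y", "z"),
                          function(k, ax) paste0("i", k, ax))))
      )
    )
    samples <- tibble::new_tibble(cols, nrow = n)

    ev_t <- c(0, rbind(ep$start, ep$end))
    ev_kind <- c("head_in", rep(c("camera_start", "camera_stop"), nrow(ep)))
    ord <- order(ev_t)
    events <- tibble::tibble(t = ev_t[ord], kind = ev_kind[ord])

    trial_recording(
      surgeon_id = surgeon_id, group = profile$group,
      exercise_id = exercise_id, sample_rate = sample_rate,
      samples = samples, events = events
    )
  })
}

# lognormal with given arithmetic mean and cv
rlnorm_mean_cv <- function(n, mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# unit-mean lognormal multiplier (1 exactly when cv = 0)
lnorm_mult <- function(cv) {
  if (cv <= 0) return(1)
  rlnorm_mean_cv(1L, 1, cv)
}

# alternating renewal: gap ~ Gamma(shape, mean cint), dur ~ Gamma(shape, mean cdur);
# only episodes fully inside [0, comp_time] are kept
draw_episodes <- function(comp_time, cint, cdur, gap_shape, dur_shape) {
  expected <- comp_time / (cint + cdur)
  block <- max(8L, ceiling(expected + 4 * sqrt(expected + 1)))
  gaps <- numeric(0); durs <- numeric(0)
  repeat {
    gaps <- c(gaps, rgamma(block, shape = gap_shape, scale = cint / gap_shape))
    durs <- c(durs, rgamma(block, shape = dur_shape, scale = cdur / dur_shape))
    if (sum(gaps) + sum(durs) > comp_time) break
  }
  cyc_end <- cumsum(gaps + durs)
  start <- cyc_end - durs
  keep <- cyc_end <= comp_time
  new_episodes(start[keep], cyc_end[keep])
}

endoscope_track <- function(t, ep, endo_speed, origin = c(0, 0, 0.12)) {
  n <- length(t)
  pos <- matrix(rep(origin, each = n), ncol = 3L)
  if (nrow(ep) == 0L || endo_speed <= 0) return(pos)
  for (j in seq_len(nrow(ep))) {
    u <- rnorm(3L)
    u <- u / sqrt(sum(u^2))
    moved <- endo_speed * pmin(pmax(t - ep$start[j], 0), ep$end[j] - ep$start[j])
    pos <- pos + outer(moved, u)
  }
  pos
}

# constant-speed path with a slowly wandering heading; polyline length is
# close to path_speed * span at any sampling rate (no fractal roughness)
instrument_track <- function(t, path_speed, sample_rate, origin = c(0, 0, 0.05)) {
  n <- length(t)
  w <- max(3L, round(sample_rate)) # ~1 s heading smoothing
  raw <- matrix(rnorm(3L * (n + w)), ncol = 3L)
  kern <- rep(1 / w, w)
  sm <- vapply(1:3, function(j) {
    as.numeric(stats::filter(raw[, j], kern, sides = 1L))[(w + 1L):(w + n)]
  }, numeric(n))
  sm <- matrix(sm, ncol = 3L)
  norms <- sqrt(rowSums(sm^2))
  norms[norms == 0] <- 1
  heading <- sm / norms
  dt <- diff(t)
  steps <- heading[-1L, , drop = FALSE] * (path_speed * dt)
  pos <- rbind(c(0, 0, 0), apply(steps, 2L, cumsum))
  if (n == 2L) pos <- rbind(c(0, 0, 0), matrix(steps, ncol = 3L))
  sweep(pos, 2L, origin, `+`)
}

hand_track <- function(n, sigma, centroid) {
  sweep(matrix(rnorm(3L * n, sd = sigma), ncol = 3L), 2L, centroid, `+`)
}

# one row per trial; seeds are drawn once from the spec seed so that every
# consumer (in-memory cohort, on-disk cohort, streamed metrics) sees the
# identical cohort
cohort_plan <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  sizes <- spec$group_sizes
  groups <- rep(experience_groups(), times = sizes)
  surgeon_id <- sprintf("S%02d", seq_along(groups))
  grid <- expand.grid(surgeon_idx = seq_along(groups),
                      exercise_id = spec$exercises,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  seeds <- withr::with_seed(spec$seed,
                            sample.int(.Machine$integer.max, nrow(grid)))
  tibble::tibble(
    surgeon_id = surgeon_id[grid$surgeon_idx],
    group = groups[grid$surgeon_idx],
    exercise_id = grid$exercise_id,
    seed = seeds
  )
}

#' Generate a synthetic cohort in memory
#'
#' One trial per surgeon per exercise; surgeons keep their group assignment
#' across exercises. Fully deterministic given `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return List with `trials` (list of [trial_recording()]s) and `manifest`
#'   (tibble: surgeon_id, group, exercise_id, seed).
#' @export
generate_cohort <- function(spec) {
  plan <- cohort_plan(spec)
  trials <- lapply(seq_len(nrow(plan)), function(i) {
    generate_trial(
      profile = spec$profiles[[plan$exercise_id[i]]][[plan$group[i]]],
      surgeon_id = plan$surgeon_id[i], exercise_id = plan$exercise_id[i],
      sample_rate = spec$sample_rate, seed = plan$seed[i]
    )
  })
  list(trials = trials, manifest = plan)
}

#' Write a synthetic cohort to disk
#'
#' Streams trials to `dir/<surgeon>/<exercise>/` (one [write_trial()]
#' directory each) without holding the whole cohort in memory, and writes
#' `manifest.json` listing every trial with its generating seed.
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory.
#' @return The manifest tibble, invisibly.
#' @export
write_cohort <- function(spec, dir) {
  plan <- cohort_plan(spec)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(plan))) {
    tr <- generate_trial(
      profile = spec$profiles[[plan$exercise_id[i]]][[plan$group[i]]],
      surgeon_id = plan$surgeon_id[i], exercise_id = plan$exercise_id[i],
      sample_rate = spec$sample_rate, seed = plan$seed[i]
    )
    write_trial(tr, file.path(dir, plan$surgeon_id[i],
                              gsub("[^A-Za-z0-9._-]+", "_", plan$exercise_id[i])))
  }
  jsonlite::write_json(plan, file.path(dir, "manifest.json"),
                       dataframe = "rows", digits = NA, pretty = TRUE)
  invisible(plan)
}

#' Simulate a cohort and return its metric table directly
#'
#' Equivalent to [generate_cohort()] followed by [cohort_metrics()] and
#' [add_surrogate_score()], but streams trial by trial so arbitrarily large
#' cohorts fit in memory.
#'
#' @param spec A [cohort_spec()].
#' @param add_score Attach the surrogate overall score (default `TRUE`).
#' @inheritParams cohort_metrics
#' @return Metric tibble, one row per trial.
#' @export
simulate_metrics <- function(spec, add_score = TRUE,
                             mwr_mode = c("scaled_max", "percentile"),
                             cint_convention = c("gap", "start_to_start")) {
  mwr_mode <- match.arg(mwr_mode)
  cint_convention <- match.arg(cint_convention)
  plan <- cohort_plan(spec)
  rows <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    tr <- generate_trial(
      profile = spec$profiles[[plan$exercise_id[i]]][[plan$group[i]]],
      surgeon_id = plan$surgeon_id[i], exercise_id = plan$exercise_id[i],
      sample_rate = spec$sample_rate, seed = plan$seed[i]
    )
    rows[[i]] <- compute_metric_set(tr, mwr_mode = mwr_mode,
                                    cint_convention = cint_convention)
  }
  tbl <- dplyr::bind_rows(rows)
  if (add_score) tbl <- add_surrogate_score(tbl)
  tbl
}

#' Surrogate overall score
#'
#' A documented composite standing in for proprietary simulator scores (it is
#' NOT that score): the average of `100 * (1 - minmax(comp_time))` and
#' `100 * (1 - minmax(eom))` over cohort bounds, so the fastest, most
#' economical trial scores 100 and the slowest, least economical scores 0.
#' Monotonically non-increasing in each input holding the other fixed.
#'
#' @param comp_time,eom Numeric vectors (same length), seconds and meters.
#' @param bounds List with elements `comp_time = c(min, max)` and
#'   `eom = c(min, max)`; defaults to the range of the supplied vectors.
#' @return Score vector in `[0, 100]`. A degenerate cohort range contributes
#'   a flat 50 for that component, with a warning.
#' @export
surrogate_overall_score <- function(comp_time, eom, bounds = NULL) {
  if (any(comp_time <= 0, na.rm = TRUE)) stop_domain("comp_time must be > 0")
  if (is.null(bounds)) {
    bounds <- list(comp_time = range(comp_time, na.rm = TRUE),
                   eom = range(eom, na.rm = TRUE))
  }
  component <- function(x, b, name) {
    span <- b[2L] - b[1L]
    if (!is.finite(span) || span <= 0) {
      sm_warn(sprintf("degenerate cohort range for %s; component fixed at 50", name))
      return(rep(50, length(x)))
    }
    100 * (1 - pmin(pmax((x - b[1L]) / span, 0), 1))
  }
  (component(comp_time, bounds$comp_time, "comp_time") +
      component(eom, bounds$eom, "eom")) / 2
}

#' Attach surrogate overall scores to a metric table
#'
#' Fills the `overall_score` column from [surrogate_overall_score()], with
#' min/max bounds taken within each exercise (trials are only comparable to
#' other trials of the same exercise).
#'
#' @param metrics Metric tibble from [cohort_metrics()]/[simulate_metrics()].
#' @param by_exercise Normalize within exercise (default) or over the whole
#'   table.
#' @return The metric tibble with `overall_score` populated.
#' @export
add_surrogate_score <- function(metrics, by_exercise = TRUE) {
  if (by_exercise) {
    metrics <- dplyr::mutate(
      dplyr::group_by(metrics, .data$exercise_id),
      overall_score = surrogate_overall_score(.data$comp_time, .data$eom)
    )
    dplyr::ungroup(metrics)
  } else {
    dplyr::mutate(metrics,
                  overall_score = surrogate_overall_score(.data$comp_time, .data$eom))
  }
}
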