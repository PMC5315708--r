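#' Configuration for kinematic camera-episode detection
#'
#' Tuning knobs for [episodes_from_kinematics()]. The defaults reflect
#' plausible console endoscope dynamics: movements slower than 2 mm/s are
#' treated as hold, detections shorter than 0.1 s as jitter, and pauses
#' shorter than 0.2 s as part of one continuous repositioning.
#'
#' @param speed_threshold Endoscope speed above which the camera is considered
#'   moving, in m/s.
#' @param min_episode Minimum retained episode length, seconds.
#' @param merge_gap Candidate episodes separated by less than this gap
#'   (seconds) are merged before the length filter is applied.
#' @param smoothing_window Moving-average window applied to the speed signal,
#'   in samples; must be odd.
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(speed_threshold = 0.002, min_episode = 0.10,
                                merge_gap = 0.20, smoothing_window = 5L) {
  assert_positive_scalar(speed_threshold, "speed_threshold")
  assert_positive_scalar(min_episode, "min_episode")
  assert_positive_scalar(merge_gap, "merge_gap")
  if (!is_scalar_number(smoothing_window) || smoothing_window < 1 ||
      smoothing_window != round(smoothing_window) || smoothing_window %% 2 == 0) {
    stop_config("`smoothing_window` must be a positive odd integer (samples)")
  }
  structure(
    list(speed_threshold = speed_threshold, min_episode = min_episode,
         merge_gap = merge_gap, smoothing_window = as.integer(smoothing_window)),
    class = "segmentation_config"
  )
}

new_episodes <- function(start = numeric(0), end = numeric(0)) {
  tibble::tibble(start = as.numeric(start), end = as.numeric(end))
}

#' Validate a camera-episode table
#'
#' Episodes must have `end > start`, be sorted by `start`, and be pairwise
#' non-overlapping.
#'
#' @param episodes Tibble with numeric columns `start` and `end` (seconds).
#' @return The episodes, invisibly, if valid; otherwise an error.
#' @export
validate_episodes <- function(episodes) {
  if (!all(c("start", "end") %in% names(episodes))) {
    stop_validation("episodes must have columns `start` and `end`")
  }
  if (nrow(episodes)) {
    if (any(!(episodes$end > episodes$start))) {
      stop_validation("each episode must satisfy end > start")
    }
    if (is.unsorted(episodes$start, strictly = FALSE)) {
      stop_validation("episodes must be sorted by start time")
    }
    if (nrow(episodes) > 1L &&
        any(episodes$start[-1L] < episodes$end[-nrow(episodes)])) {
      stop_validation("episodes must be pairwise non-overlapping")
    }
  }
  invisible(episodes)
}

#' Camera episodes from system event markers
#'
#' Pairs each `camera_start` with the next `camera_stop`. This is the primary
#' segmentation path: when the platform records camera-movement events, they
#' are trusted as ground truth. A `camera_stop` with no open episode is
#' skipped with a warning; a `camera_start` never closed is clamped to the
#' trial duration with a warning. Episodes are clipped to `[0, duration]`.
#'
#' @param events Time-ordered event tibble (`t`, `kind`); non-camera kinds are
#'   ignored.
#' @param duration Trial duration in seconds.
#' @return Episode tibble (`start`, `end`), sorted and non-overlapping.
#' @export
#' @examples
#' ev <- tibble::tibble(
#'   t = c(1, 2, 4, 6), kind = c("camera_start", "camera_stop",
#'                               "camera_start", "camera_stop")
#' )
#' episodes_from_events(ev, duration = 10)
episodes_from_events <- function(events, duration) {
  assert_positive_scalar(duration, "duration")
  cam <- events[events$kind %in% c("camera_start", "camera_stop"), , drop = FALSE]
  cam <- cam[order(cam$t), , drop = FALSE]
  starts <- numeric(0)
  ends <- numeric(0)
  open_t <- NA_real_
  for (i in seq_len(nrow(cam))) {
    if (cam$kind[i] == "camera_start") {
      if (!is.na(open_t)) {
        sm_warn(sprintf(
          "camera_start at t=%.6g while an episode opened at t=%.6g is still open; closing the first at the new start",
          cam$t[i], open_t
        ))
        starts <- c(starts, open_t); ends <- c(ends, cam$t[i])
      }
      open_t <- cam$t[i]
    } else {
      if (is.na(open_t)) {
        sm_warn(sprintf("camera_stop at t=%.6g with no open episode; skipped", cam$t[i]))
      } else {
        starts <- c(starts, open_t); ends <- c(ends, cam$t[i])
        open_t <- NA_real_
      }
    }
  }
  if (!is.na(open_t)) {
    sm_warn(sprintf(
      "camera_start at t=%.6g never closed; episode clamped to trial duration %.6g",
      open_t, duration
    ))
    starts <- c(starts, open_t); ends <- c(ends, duration)
  }
  ep <- new_episodes(pmax(starts, 0), pmin(ends, duration))
  ep <- ep[ep$end > ep$start, , drop = FALSE]
  validate_episodes(ep)
  ep
}

#' Camera episodes detected from endoscope kinematics
#'
#' Fallback segmentation for recordings that lack camera events. Endoscope
#' speed is estimated by centered finite differences of position (edge
#' replication at the two boundary samples), smoothed by a moving average of
#' `smoothing_window` samples. Maximal runs with smoothed speed above
#' `speed_threshold` become candidate episodes; candidates separated by less
#' than `merge_gap` are merged, then candidates shorter than `min_episode`
#' are discarded.
#'
#' @param samples Kinematic sample tibble (needs `t`, `ex`, `ey`, `ez`),
#'   strictly increasing in `t`.
#' @param cfg A [segmentation_config()].
#' @return Episode tibble (`start`, `end`), sorted and non-overlapping.
#'   Empty when fewer than 2 samples are supplied.
#' @export
episodes_from_kinematics <- function(samples, cfg = segmentation_config()) {
  stopifnot(inherits(cfg, "segmentation_config"))
  n <- nrow(samples)
  if (is.null(n) || n < 2L) return(new_episodes())
  t <- samples$t
  if (any(diff(t) <= 0)) stop_validation("timestamps must be strictly increasing")
  pos <- cbind(samples$ex, samples$ey, samples$ez)

  # centered differences; first/last sample fall back to one-sided
  idx_prev <- c(1L, 1L:(n - 1L))
  idx_next <- c(2L:n, n)
  dt <- t[idx_next] - t[idx_prev]
  vel <- (pos[idx_next, , drop = FALSE] - pos[idx_prev, , drop = FALSE]) / dt
  speed <- sqrt(rowSums(vel^2))

  w <- cfg$smoothing_window
  if (w > 1L && n > 1L) {
    half <- (w - 1L) %/% 2L
    padded <- c(rep(speed[1L], half), speed, rep(speed[n], half))
    speed <- as.numeric(stats::filter(padded, rep(1 / w, w), sides = 2L))[(half + 1L):(half + n)]
  }

  above <- speed > cfg$speed_threshold
  if (!any(above)) return(new_episodes())
  r <- rle(above)
  stops <- cumsum(r$lengths)
  starts_idx <- stops - r$lengths + 1L
  keep <- r$values
  cand_start <- t[starts_idx[keep]]
  cand_end <- t[stops[keep]]

  # merge candidates separated by < merge_gap
  if (length(cand_start) > 1L) {
    ms <- cand_start[1L]; me <- cand_end[1L]
    out_s <- numeric(0); out_e <- numeric(0)
    for (i in 2L:length(cand_start)) {
      if (cand_start[i] - me < cfg$merge_gap) {
        me <- cand_end[i]
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- cand_start[i]; me <- cand_end[i]
      }
    }
    cand_start <- c(out_s, ms); cand_end <- c(out_e, me)
  }

  keep_len <- (cand_end - cand_start) >= cfg$min_episode
  ep <- new_episodes(cand_start[keep_len], cand_end[keep_len])
  validate_episodes(ep)
  ep
}
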