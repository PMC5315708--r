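#' Read a trial recording from a directory
#'
#' A trial lives in a directory of three plain-text files:
#' \describe{
#'   \item{`kinematics.csv`}{header `t,lx,ly,lz,rx,ry,rz,ex,ey,ez,i1x,...`
#'     (one `i<k>x,i<k>y,i<k>z` triplet per instrument); meters, seconds.}
#'   \item{`events.csv`}{header `t,kind`.}
#'   \item{`meta.json`}{keys `surgeon_id`, `group`, `exercise_id`,
#'     `sample_rate_hz`, `units` (must be `"m"`), optional `overall_score`.}
#' }
#' All content is validated on the way in; see [trial_recording()].
#'
#' @param path Directory containing the three files.
#' @return A validated [trial_recording()].
#' @export
#' @seealso [write_trial()]
#' @examples
#' # bundled synthetic example trial (generated by generate_trial())
#' demo <- system.file("extdata", "example_trial", package = "scopemetrics")
#' tr <- read_trial(demo)
#' compute_metric_set(tr)
read_trial <- function(path) {
  if (!dir.exists(path)) stop_format(sprintf("trial directory not found: %s", path))
  files <- file.path(path, c("kinematics.csv", "events.csv", "meta.json"))
  missing <- files[!file.exists(files)]
  if (length(missing)) {
    stop_format(sprintf("missing trial file(s): %s", paste(missing, collapse = ", ")))
  }

  meta <- jsonlite::read_json(files[3L], simplifyVector = TRUE)
  required <- c("surgeon_id", "group", "exercise_id", "sample_rate_hz", "units")
  miss <- setdiff(required, names(meta))
  if (length(miss)) {
    stop_format(sprintf("meta.json missing key(s): %s", paste(miss, collapse = ", ")))
  }
  if (!identical(meta$units, "m")) {
    stop_validation(sprintf("unsupported units \"%s\"; positions must be in meters (\"m\")",
                            as.character(meta$units)))
  }

  samples <- readr::read_csv(files[1L], col_types = readr::cols(.default = readr::col_double()),
                             progress = FALSE)
  events <- readr::read_csv(files[2L],
                            col_types = readr::cols(t = readr::col_double(),
                                                    kind = readr::col_character()),
                            progress = FALSE)

  trial_recording(
    surgeon_id = as.character(meta$surgeon_id),
    group = as.character(meta$group),
    exercise_id = as.character(meta$exercise_id),
    sample_rate = as.numeric(meta$sample_rate_hz),
    samples = samples,
    events = events,
    overall_score = if ("overall_score" %in% names(meta)) as.numeric(meta$overall_score) else NULL
  )
}

#' Write a trial recording to a directory
#'
#' Inverse of [read_trial()]: writes `kinematics.csv`, `events.csv`, and
#' `meta.json` at full numeric precision, so read-after-write reproduces the
#' trial content exactly.
#'
#' @param trial A [trial_recording()].
#' @param path Target directory (created, recursively, if absent).
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "trial_recording"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop_format(sprintf("cannot create trial directory: %s", path))

  readr::write_csv(trial$samples, file.path(path, "kinematics.csv"), progress = FALSE)
  readr::write_csv(trial$events, file.path(path, "events.csv"), progress = FALSE)

  meta <- list(
    surgeon_id = trial$surgeon_id,
    group = trial$group,
    exercise_id = trial$exercise_id,
    sample_rate_hz = trial$sample_rate,
    units = "m"
  )
  if (!is.null(trial$overall_score)) meta$overall_score <- trial$overall_score
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
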