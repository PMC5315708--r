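#' Read a pipeline configuration
#'
#' Loads a YAML pipeline configuration and fills defaults. Recognised blocks:
#' \describe{
#'   \item{`cohort`}{`exercises` (list; default the 25 simulator exercises),
#'     `seed`, `sample_rate`, `group_sizes` (named `new`/`intermediate`/
#'     `experienced`), optional `difficulty` vector.}
#'   \item{`segmentation`}{`speed_threshold`, `min_episode`, `merge_gap`,
#'     `smoothing_window`, plus `use_kinematics` to opt into the kinematic
#'     detector instead of event markers.}
#'   \item{`metrics`}{`mwr_mode` (`scaled_max`/`percentile`),
#'     `cint_convention` (`gap`/`start_to_start`).}
#'   \item{`validity`}{`variant` (`student`/`welch`), `alpha`, `paired`.}
#'   \item{`output_dir`}{where reports are written.}
#' }
#'
#' @param path YAML file path, or `NULL` for all defaults.
#' @param overrides Named list merged over the file contents (flags beat
#'   config).
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path = NULL, overrides = list()) {
  if (!is.null(path) && !file.exists(path)) {
    stop_config(sprintf("config file not found: %s", path))
  }
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) stop_config("config file must contain a YAML mapping")
  cfg <- utils::modifyList(cfg, overrides)
  cohort <- cfg$cohort %||% list()
  seg <- cfg$segmentation %||% list()
  met <- cfg$metrics %||% list()
  val <- cfg$validity %||% list()
  gs <- cohort$group_sizes %||% list(new = 18L, intermediate = 8L, experienced = 13L)
  structure(
    list(
      cohort = list(
        exercises = as.character(cohort$exercises %||% dvss_exercises()),
        seed = cohort$seed,
        sample_rate = cohort$sample_rate %||% 50,
        group_sizes = c(new = as.integer(gs$new), intermediate = as.integer(gs$intermediate),
                        experienced = as.integer(gs$experienced)),
        difficulty = cohort$difficulty
      ),
      segmentation = segmentation_config(
        speed_threshold = seg$speed_threshold %||% 0.002,
        min_episode = seg$min_episode %||% 0.10,
        merge_gap = seg$merge_gap %||% 0.20,
        smoothing_window = seg$smoothing_window %||% 5L
      ),
      use_kinematics = isTRUE(seg$use_kinematics),
      mwr_mode = met$mwr_mode %||% "scaled_max",
      cint_convention = met$cint_convention %||% "gap",
      variant = val$variant %||% "student",
      alpha = val$alpha %||% 0.05,
      paired = val$paired %||% TRUE,
      output_dir = cfg$output_dir %||% "results"
    ),
    class = "pipeline_config"
  )
}

config_cohort_spec <- function(config) {
  if (is.null(config$cohort$seed)) {
    stop_config("a seed is required whenever simulation is invoked")
  }
  cohort_spec(
    exercises = config$cohort$exercises,
    seed = config$cohort$seed,
    group_sizes = config$cohort$group_sizes,
    sample_rate = config$cohort$sample_rate,
    difficulty = config$cohort$difficulty
  )
}

config_hash <- function(config) {
  # provenance: stable fingerprint of the effective configuration
  s <- paste(utils::capture.output(utils::str(config, digits.d = 15)), collapse = "\n")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 251 + 1)) %% .Machine$integer.max)
}

log_line <- function(level, msg) {
  message(sprintf("[scopemetrics] %s: %s", level, msg))
}

#' Simulate a cohort to disk
#'
#' Writes the trial directories and `manifest.json` (including the config
#' hash and seed) under `dir`.
#'
#' @param config A `pipeline_config` (see [read_pipeline_config()]).
#' @param dir Output cohort directory (default `<output_dir>/cohort`).
#' @return The cohort directory, invisibly.
#' @export
run_simulate <- function(config, dir = file.path(config$output_dir, "cohort")) {
  spec <- config_cohort_spec(config)
  log_line("info", sprintf("simulating %d surgeons x %d exercises (seed %d)",
                           sum(spec$group_sizes), length(spec$exercises), spec$seed))
  plan <- write_cohort(spec, dir)
  meta <- list(seed = spec$seed, config_hash = config_hash(config),
               n_trials = nrow(plan))
  jsonlite::write_json(meta, file.path(dir, "run.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Extract metrics for a cohort directory
#'
#' Reads every trial under `cohort_dir`, computes its metric set, attaches
#' the surrogate overall score, and writes `metrics.csv` under the output
#' directory. Unreadable trials are skipped with a logged warning; the call
#' fails only if every trial fails.
#'
#' @param config A `pipeline_config`.
#' @param cohort_dir Cohort directory (default `<output_dir>/cohort`).
#' @return The metric tibble, invisibly; also written as CSV.
#' @export
run_metrics <- function(config, cohort_dir = file.path(config$output_dir, "cohort")) {
  paths <- list.dirs(cohort_dir, recursive = TRUE, full.names = TRUE)
  paths <- paths[file.exists(file.path(paths, "meta.json"))]
  if (!length(paths)) stop_format(sprintf("no trials under %s", cohort_dir))
  rows <- list()
  for (p in paths) {
    row <- tryCatch({
      tr <- read_trial(p)
      ep <- if (config$use_kinematics) {
        episodes_from_kinematics(tr$samples, config$segmentation)
      } else NULL
      withCallingHandlers(
        compute_metric_set(tr, episodes = ep, mwr_mode = config$mwr_mode,
                           cint_convention = config$cint_convention),
        scopemetrics_warning = function(w) {
          log_line("warn", sprintf("%s: %s", p, conditionMessage(w)))
          invokeRestart("muffleWarning")
        }
      )
    }, error = function(e) {
      log_line("warn", sprintf("skipping unreadable trial %s: %s", p, conditionMessage(e)))
      NULL
    })
    if (!is.null(row)) rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows)) stop_format("all trials failed to produce metrics")
  tbl <- add_surrogate_score(dplyr::bind_rows(rows))
  tbl <- dplyr::arrange(tbl, .data$exercise_id, .data$surgeon_id)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(tbl, file.path(config$output_dir, "metrics.csv"), progress = FALSE)
  invisible(tbl)
}

#' Run the construct-validity analysis and write reports
#'
#' From a metric table (or `metrics.csv` under the output directory) writes:
#' `table_cfrq.csv`, `table_cdur.csv`, `table_cint.csv` (per-exercise group
#' means, SDs, pairwise p-values, correlations, significance flags),
#' `discrimination.csv` (normalized new-vs-experienced discrimination with
#' rank, dispersion and the pairwise p matrix), and `summary.json`
#' (threshold, comparison count, config hash). With a single exercise the
#' discrimination step is skipped with a warning (normalization needs >= 2).
#'
#' @param config A `pipeline_config`.
#' @param metrics Optional metric tibble; read from disk when `NULL`.
#' @return List with `tables` and `discrimination`, invisibly.
#' @export
run_validity <- function(config, metrics = NULL) {
  if (is.null(metrics)) {
    path <- file.path(config$output_dir, "metrics.csv")
    if (!file.exists(path)) stop_format(sprintf("metrics table not found: %s", path))
    metrics <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  if (length(unique(metrics$group)) < 2L) {
    stop_config("validity analysis needs at least 2 experience groups")
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- validity_tables(metrics, alpha = config$alpha, variant = config$variant)
  for (m in names(tabs)) {
    readr::write_csv(tabs[[m]], file.path(config$output_dir, sprintf("table_%s.csv", m)),
                     progress = FALSE)
  }
  disc <- NULL
  if (length(unique(metrics$exercise_id)) >= 2L &&
      all(c("new", "experienced") %in% metrics$group)) {
    disc <- discrimination(metrics, paired = config$paired)
    pw <- tibble::as_tibble(disc$pairwise_p)
    names(pw) <- paste0("p_vs_", names(pw))
    readr::write_csv(dplyr::bind_cols(disc$ranking, pw),
                     file.path(config$output_dir, "discrimination.csv"),
                     progress = FALSE)
  } else {
    log_line("warn", "discrimination skipped: needs >= 2 exercises and both new and experienced groups")
  }
  jsonlite::write_json(
    list(alpha = config$alpha, variant = config$variant,
         n_comparisons = attr(tabs, "n_comparisons"),
         config_hash = config_hash(config)),
    file.path(config$output_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(list(tables = tabs, discrimination = disc))
}

#' Run the full pipeline: simulate, extract metrics, analyse
#'
#' @param config_path YAML config path or `NULL` for defaults.
#' @param seed Seed override (takes precedence over the config file).
#' @param output_dir Output directory override.
#' @return The [run_validity()] result, invisibly.
#' @export
run_pipeline <- function(config_path = NULL, seed = NULL, output_dir = NULL) {
  overrides <- list()
  if (!is.null(output_dir)) overrides$output_dir <- output_dir
  config <- read_pipeline_config(config_path, overrides)
  if (!is.null(seed)) config$cohort$seed <- seed
  run_simulate(config)
  metrics <- run_metrics(config)
  run_validity(config, metrics)
}
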