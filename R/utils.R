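#' @importFrom rlang abort warn %||% .data
#' @importFrom stats sd var quantile rnorm rgamma rlnorm runif pt qt
NULL

# Classed conditions so callers (and the CLI) can distinguish bad input from bugs.
stop_format <- function(msg, ...) abort(msg, class = "scopemetrics_format_error", ...)
stop_validation <- function(msg, ...) abort(msg, class = "scopemetrics_validation_error", ...)
stop_domain <- function(msg, ...) abort(msg, class = "scopemetrics_domain_error", ...)
stop_config <- function(msg, ...) abort(msg, class = "scopemetrics_config_error", ...)

sm_warn <- function(msg) warn(msg, class = "scopemetrics_warning")

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

assert_positive_scalar <- function(x, name) {
  if (!is_scalar_number(x) || x <= 0) {
    stop_config(sprintf("`%s` must be a single positive finite number", name))
  }
  invisible(x)
}

#' Surgeon experience groups
#'
#' Group labels follow the usual case-volume convention for robot-assisted
#' surgery cohorts: "new" (< 20 procedures), "intermediate" (21-150), and
#' "experienced" (> 150).
#'
#' @return Character vector of the three group labels, ordered by experience.
#' @export
experience_groups <- function() c("new", "intermediate", "experienced")

#' Event kinds recognised in a trial event stream
#'
#' Discrete console events recorded alongside kinematics: camera (endoscope)
#' movement start/stop, master clutch engage/release, and head-in/head-out
#' of the surgeon console.
#'
#' @return Character vector of the six recognised event kinds.
#' @export
event_kinds <- function() {
  c("camera_start", "camera_stop", "clutch_start", "clutch_stop",
    "head_in", "head_out")
}
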