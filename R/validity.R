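camera_metric_names <- function() c("cfrq", "cdur", "cint")

all_metric_names <- function() {
  c("cfrq", "cdur", "cint", "comp_time", "eom", "mwr", "overall_score")
}

#' Two-sample t test (pooled Student or Welch)
#'
#' Thin, missing-value-aware wrapper used throughout the group comparisons.
#' The default is the pooled-variance Student test with
#' `df = n_a + n_b - 2`; Welch (Satterthwaite df) is available for
#' robustness reporting. P-values are two-sided. Results that cannot be
#' computed (fewer than 2 finite values in either sample, or zero pooled
#' variance) are flagged rather than raised, so they propagate as missing
#' p-values in downstream tables.
#'
#' @param a,b Numeric samples; `NA`s are dropped.
#' @param variant `"student"` (default) or `"welch"`.
#' @return One-row tibble: `t`, `df`, `p`, `n_a`, `n_b`, `computable`.
#' @export
#' @examples
#' two_sample_t(c(1, 2, 3), c(4, 5, 6)) # t = -3.674, df = 4, p ~ 0.0213
two_sample_t <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  not_computable <- tibble::tibble(
    t = NA_real_, df = NA_real_, p = NA_real_,
    n_a = length(a), n_b = length(b), computable = FALSE
  )
  if (length(a) < 2L || length(b) < 2L) return(not_computable)
  if (var(a) == 0 && var(b) == 0) return(not_computable) # t undefined
  ht <- tryCatch(stats::t.test(a, b, var.equal = (variant == "student")),
                 error = function(e) NULL)
  if (is.null(ht)) return(not_computable)
  tibble::tibble(
    t = unname(ht$statistic), df = unname(ht$parameter),
    p = ht$p.value, n_a = length(a), n_b = length(b), computable = TRUE
  )
}

#' Pearson correlation with t-based p-value
#'
#' Pearson's r with the usual two-sided significance test
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' Incomplete pairs are dropped; fewer than 3 complete pairs or zero
#' variance in either variable flags the result as not computable.
#'
#' @param x,y Numeric vectors of equal length.
#' @return One-row tibble: `r`, `p`, `n`, `computable`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop_domain("`x` and `y` must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  not_computable <- tibble::tibble(r = NA_real_, p = NA_real_, n = n,
                                   computable = FALSE)
  if (n < 3L || var(x) == 0 || var(y) == 0) return(not_computable)
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = n,
                 computable = TRUE)
}

#' Min-max normalization across exercises
#'
#' Rescales a vector of per-exercise means onto `[0, 1]`:
#' `(x - min(x)) / (max(x) - min(x))`. With a degenerate (constant) input the
#' output is all zeros and the `degenerate` flag is set.
#'
#' @param x Numeric vector of per-exercise means (length >= 2, finite).
#' @return List: `values` (normalized vector, attains 0 and 1 unless
#'   degenerate), `x_min`, `x_max`, `degenerate`.
#' @export
minmax_normalize <- function(x) {
  if (length(x) < 2L) stop_domain("min-max normalization needs >= 2 values")
  if (any(!is.finite(x))) stop_domain("min-max normalization needs finite values")
  x_min <- min(x); x_max <- max(x)
  if (x_max == x_min) {
    return(list(values = rep(0, length(x)), x_min = x_min, x_max = x_max,
                degenerate = TRUE))
  }
  list(values = (x - x_min) / (x_max - x_min), x_min = x_min, x_max = x_max,
       degenerate = FALSE)
}

group_stats <- function(x) {
  x <- x[is.finite(x)]
  c(mean = if (length(x)) mean(x) else NA_real_,
    sd = if (length(x) > 1L) sd(x) else NA_real_,
    n = length(x))
}

#' Per-exercise group comparison for one metric
#'
#' One row of the construct-validity tables: per-group mean, sample SD
#' (n - 1 denominator), and effective n after missing-value exclusion, plus
#' the three pairwise two-sided t tests (new vs intermediate, new vs
#' experienced, intermediate vs experienced). Missing metric values (e.g.
#' CDur/CInt for zero-episode trials) are excluded per comparison.
#'
#' @param table Metric tibble (one row per surgeon x exercise).
#' @param metric Metric column name, one of
#'   `cfrq, cdur, cint, comp_time, eom, mwr, overall_score`.
#' @param exercise Exercise id present in `table`.
#' @param variant t-test variant, see [two_sample_t()].
#' @return One-row tibble: `exercise_id`, `metric`, `mean_*`, `sd_*`, `n_*`
#'   per group, and `p_new_vs_int`, `p_new_vs_exp`, `p_int_vs_exp`.
#' @export
group_comparisons <- function(table, metric, exercise,
                              variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (!metric %in% names(table)) stop_domain(sprintf("no metric column `%s`", metric))
  rows <- table[table$exercise_id == exercise, , drop = FALSE]
  if (nrow(rows) == 0L) stop_domain(sprintf("exercise \"%s\" not in table", exercise))
  vals <- lapply(experience_groups(), function(g) rows[[metric]][rows$group == g])
  names(vals) <- experience_groups()
  st <- lapply(vals, group_stats)
  pair_p <- function(g1, g2) two_sample_t(vals[[g1]], vals[[g2]], variant)$p
  tibble::tibble(
    exercise_id = exercise, metric = metric,
    mean_new = st$new[["mean"]], sd_new = st$new[["sd"]], n_new = st$new[["n"]],
    mean_int = st$intermediate[["mean"]], sd_int = st$intermediate[["sd"]],
    n_int = st$intermediate[["n"]],
    mean_exp = st$experienced[["mean"]], sd_exp = st$experienced[["sd"]],
    n_exp = st$experienced[["n"]],
    p_new_vs_int = pair_p("new", "intermediate"),
    p_new_vs_exp = pair_p("new", "experienced"),
    p_int_vs_exp = pair_p("intermediate", "experienced")
  )
}

per_exercise_group_means <- function(table, metric, groups) {
  exercises <- unique(table$exercise_id)
  out <- lapply(groups, function(g) {
    vapply(exercises, function(ex) {
      v <- table[[metric]][table$exercise_id == ex & table$group == g]
      v <- v[is.finite(v)]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
  })
  names(out) <- groups
  out$exercises <- exercises
  out
}

#' Normalized group discrimination across exercises
#'
#' Quantifies how well each metric separates two experience groups across a
#' battery of exercises. For each metric, the per-exercise group means of
#' both groups are min-max normalized together (shared min/max, so the
#' between-group difference survives normalization), and the discrimination
#' score is `d = |mean(group1 normalized means) - mean(group2 normalized
#' means)|`. Per-exercise absolute differences `d_i` are retained for
#' dispersion and for pairwise metric-vs-metric t tests, paired by exercise
#' (the same exercises underlie every metric; an unpaired variant is
#' available). Output is ranked by `d`, descending. Metrics whose group
#' means are missing for more than half the exercises are excluded with a
#' warning.
#'
#' @param table Metric tibble (one row per surgeon x exercise, >= 2
#'   exercises).
#' @param metrics Metric columns to rank (default: all six kinematic/time
#'   metrics).
#' @param group_pair Character pair of groups to contrast (default new vs
#'   experienced).
#' @param paired Pair the metric-vs-metric t tests by exercise (default
#'   `TRUE`).
#' @return List of class `discrimination_result`:
#'   `ranking` (tibble metric, d, sd, rank), `per_exercise` (tibble of d_i),
#'   `pairwise_p` (symmetric matrix of metric-vs-metric p-values),
#'   `group_pair`.
#' @export
discrimination <- function(table,
                           metrics = c("cfrq", "cdur", "cint", "comp_time",
                                       "eom", "mwr"),
                           group_pair = c("new", "experienced"),
                           paired = TRUE) {
  if (length(group_pair) != 2L || !all(group_pair %in% experience_groups())) {
    stop_domain("`group_pair` must name two experience groups")
  }
  exercises <- unique(table$exercise_id)
  if (length(exercises) < 2L) {
    stop_domain("discrimination needs >= 2 exercises (min-max normalization)")
  }

  di <- list(); d <- numeric(0); sd_d <- numeric(0); kept <- character(0)
  for (m in metrics) {
    gm <- per_exercise_group_means(table, m, group_pair)
    ok <- is.finite(gm[[1L]]) & is.finite(gm[[2L]])
    if (sum(ok) < length(exercises) / 2 || sum(ok) < 2L) {
      sm_warn(sprintf(
        "metric `%s` has computable group means for only %d/%d exercises; excluded from discrimination",
        m, sum(ok), length(exercises)
      ))
      next
    }
    nm <- minmax_normalize(c(gm[[1L]][ok], gm[[2L]][ok]))
    k <- sum(ok)
    n1 <- nm$values[seq_len(k)]
    n2 <- nm$values[k + seq_len(k)]
    kept <- c(kept, m)
    d <- c(d, abs(mean(n1) - mean(n2)))
    dvec <- rep(NA_real_, length(exercises))
    dvec[ok] <- abs(n1 - n2)
    di[[m]] <- dvec
    sd_d <- c(sd_d, sd(dvec[ok]))
  }
  if (!length(kept)) stop_domain("no metric had computable group means")

  pm <- matrix(NA_real_, length(kept), length(kept),
               dimnames = list(kept, kept))
  for (i in seq_along(kept)) {
    for (j in seq_along(kept)) {
      if (i == j) { pm[i, j] <- 1; next }
      if (i > j) { pm[i, j] <- pm[j, i]; next }
      x <- di[[kept[i]]]; y <- di[[kept[j]]]
      if (paired) {
        ok <- is.finite(x) & is.finite(y)
        dd <- x[ok] - y[ok]
        if (length(dd) < 2L) {
          pm[i, j] <- NA_real_
        } else if (all(dd == 0)) {
          pm[i, j] <- 1 # identical per-exercise differences
        } else {
          pm[i, j] <- stats::t.test(dd)$p.value
        }
      } else {
        pm[i, j] <- two_sample_t(x, y)$p
      }
    }
  }

  ord <- order(d, decreasing = TRUE)
  ranking <- tibble::tibble(
    metric = kept[ord], d = d[ord], sd = sd_d[ord],
    rank = seq_along(kept)
  )
  per_exercise <- tibble::as_tibble(c(list(exercise_id = exercises), di))
  structure(
    list(ranking = ranking, per_exercise = per_exercise,
         pairwise_p = pm[kept[ord], kept[ord], drop = FALSE],
         group_pair = group_pair),
    class = "discrimination_result"
  )
}

#' @export
print.discrimination_result <- function(x, ...) {
  cat(sprintf("<discrimination_result> %s vs %s, %d exercises\n",
              x$group_pair[1L], x$group_pair[2L], nrow(x$per_exercise)))
  print(x$ranking)
  invisible(x)
}

#' Correlations of camera metrics with efficiency targets
#'
#' Per exercise, correlates each camera metric against each target
#' (completion time and overall score by default) over all surgeons pooled
#' across experience groups, via [pearson_with_p()]. Note the targets are
#' raw values: because experienced surgeons move the camera more often yet
#' finish faster, CFrq typically correlates negatively with raw completion
#' time (score-like time columns in published tables can carry the opposite
#' sign).
#'
#' @param table Metric tibble.
#' @param camera_metrics Metric columns to correlate (default CFrq, CDur,
#'   CInt).
#' @param targets Target columns (default `comp_time`, `overall_score`).
#' @return Tibble: `exercise_id`, `metric`, `target`, `r`, `p`, `n`,
#'   `computable`.
#' @export
metric_target_correlations <- function(table,
                                       camera_metrics = c("cfrq", "cdur", "cint"),
                                       targets = c("comp_time", "overall_score")) {
  exercises <- unique(table$exercise_id)
  rows <- list()
  for (ex in exercises) {
    sub <- table[table$exercise_id == ex, , drop = FALSE]
    for (m in camera_metrics) {
      for (tg in targets) {
        core <- pearson_with_p(sub[[m]], sub[[tg]])
        rows[[length(rows) + 1L]] <- tibble::tibble(
          exercise_id = ex, metric = m, target = tg,
          r = core$r, p = core$p, n = core$n, computable = core$computable
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Construct-validity tables for the camera metrics
#'
#' Builds, for each camera metric, the standard per-exercise table: group
#' means and SDs, the three pairwise p-values, and Pearson r / p against
#' completion time and overall score, plus significance flags at `alpha`.
#' No multiple-testing correction is applied (each cell is a single
#' unadjusted test, as is conventional for these tables); the comparison
#' count is returned so users can apply their own.
#'
#' @param table Metric tibble.
#' @param camera_metrics Metrics to tabulate (default CFrq, CDur, CInt).
#' @param alpha Significance threshold for the flags (default 0.05).
#' @param variant t-test variant.
#' @return List with one tibble per metric (named), and attribute
#'   `n_comparisons` (total number of tests across the tables).
#' @export
validity_tables <- function(table, camera_metrics = c("cfrq", "cdur", "cint"),
                            alpha = 0.05, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  exercises <- unique(table$exercise_id)
  corr <- metric_target_correlations(table, camera_metrics)
  out <- lapply(camera_metrics, function(m) {
    gc <- dplyr::bind_rows(lapply(exercises, function(ex) {
      group_comparisons(table, m, ex, variant)
    }))
    ct <- corr[corr$metric == m & corr$target == "comp_time",
               c("exercise_id", "r", "p")]
    names(ct) <- c("exercise_id", "r_time", "p_time")
    os <- corr[corr$metric == m & corr$target == "overall_score",
               c("exercise_id", "r", "p")]
    names(os) <- c("exercise_id", "r_score", "p_score")
    tab <- dplyr::left_join(dplyr::left_join(gc, ct, by = "exercise_id"),
                            os, by = "exercise_id")
    dplyr::mutate(
      tab,
      sig_new_vs_int = !is.na(.data$p_new_vs_int) & .data$p_new_vs_int < alpha,
      sig_new_vs_exp = !is.na(.data$p_new_vs_exp) & .data$p_new_vs_exp < alpha,
      sig_int_vs_exp = !is.na(.data$p_int_vs_exp) & .data$p_int_vs_exp < alpha,
      sig_time = !is.na(.data$p_time) & .data$p_time < alpha,
      sig_score = !is.na(.data$p_score) & .data$p_score < alpha
    )
  })
  names(out) <- camera_metrics
  attr(out, "n_comparisons") <-
    length(camera_metrics) * length(exercises) * 5L
  attr(out, "alpha") <- alpha
  out
}
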