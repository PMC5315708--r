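# Fixture builders and independent oracles shared across the test files.

# Kinematic sample table with controllable streams; every stream defaults to
# a fixed point so tests can vary exactly the one they care about.
make_samples <- function(t, endo = NULL, left = NULL, right = NULL,
                         instruments = NULL) {
  n <- length(t)
  fixed <- function(m, default) {
    if (is.null(m)) matrix(rep(default, each = n), ncol = 3) else m
  }
  endo <- fixed(endo, c(0, 0, 0.1))
  left <- fixed(left, c(-0.1, 0, 0))
  right <- fixed(right, c(0.1, 0, 0))
  if (is.null(instruments)) {
    instruments <- list(matrix(rep(c(0, 0, 0.05), each = n), ncol = 3))
  }
  cols <- list(t = t,
               lx = left[, 1], ly = left[, 2], lz = left[, 3],
               rx = right[, 1], ry = right[, 2], rz = right[, 3],
               ex = endo[, 1], ey = endo[, 2], ez = endo[, 3])
  for (k in seq_along(instruments)) {
    m <- instruments[[k]]
    cols[[paste0("i", k, "x")]] <- m[, 1]
    cols[[paste0("i", k, "y")]] <- m[, 2]
    cols[[paste0("i", k, "z")]] <- m[, 3]
  }
  tibble::as_tibble(cols)
}

make_trial <- function(t = seq(0, 10, by = 0.02), events = NULL, ...,
                       group = "new", surgeon_id = "S01",
                       exercise_id = "EX1", sample_rate = 50,
                       overall_score = NULL) {
  trial_recording(
    surgeon_id = surgeon_id, group = group, exercise_id = exercise_id,
    sample_rate = sample_rate,
    samples = make_samples(t, ...),
    events = if (is.null(events)) tibble::tibble(t = numeric(0), kind = character(0)) else events,
    overall_score = overall_score
  )
}

camera_events <- function(episodes) {
  tibble::tibble(
    t = as.vector(rbind(episodes$start, episodes$end)),
    kind = rep(c("camera_start", "camera_stop"), nrow(episodes))
  )
}

# Endoscope trajectory moving at `speed` along +x inside each episode and
# stationary outside; the analytic ground truth for the kinematic detector.
trajectory_from_episodes <- function(episodes, duration, rate, speed = 0.01) {
  t <- seq(0, duration, by = 1 / rate)
  moved <- rep(0, length(t))
  for (j in seq_len(nrow(episodes))) {
    moved <- moved + pmin(pmax(t - episodes$start[j], 0),
                          episodes$end[j] - episodes$start[j])
  }
  make_samples(t, endo = cbind(speed * moved, 0, 0.1))
}

# Monte-Carlo permutation p-value for the two-sample mean difference (for the
# pooled-variance t with fixed split sizes, |t| is monotone in |mean diff|,
# so this is the randomization p of the t statistic as well).
perm_p_two_sample <- function(a, b, B = 1e5) {
  pooled <- c(a, b)
  na <- length(a)
  obs <- abs(mean(a) - mean(b))
  stat <- vapply(seq_len(B), function(i) {
    idx <- sample(length(pooled), na)
    abs(mean(pooled[idx]) - mean(pooled[-idx]))
  }, numeric(1))
  (1 + sum(stat >= obs - 1e-12)) / (B + 1)
}

# Monte-Carlo permutation p-value for |r| under permutation of y.
perm_p_cor <- function(x, y, B = 1e5) {
  obs <- abs(cor(x, y))
  stat <- vapply(seq_len(B), function(i) abs(cor(x, sample(y))), numeric(1))
  (1 + sum(stat >= obs - 1e-12)) / (B + 1)
}

# Brute-force null-resimulation estimate of P(|T| >= |t_obs|) for the pooled
# two-sample t under a standard normal null: draws B fresh datasets, computes
# the statistic from its definition (no t distribution involved), and counts
# exceedances. Independent oracle for the analytic p-value.
sim_p_two_sample_t <- function(t_obs, na, nb, B = 1e5) {
  A <- matrix(rnorm(na * B), nrow = na)
  Bm <- matrix(rnorm(nb * B), nrow = nb)
  ma <- colMeans(A); mb <- colMeans(Bm)
  va <- (colSums(A^2) - na * ma^2) / (na - 1)
  vb <- (colSums(Bm^2) - nb * mb^2) / (nb - 1)
  sp <- sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
  stat <- abs((ma - mb) / (sp * sqrt(1 / na + 1 / nb)))
  mean(stat >= abs(t_obs))
}

# Same idea for the Pearson r significance test: independent normal x and y.
sim_p_pearson <- function(r_obs, n, B = 1e5) {
  X <- matrix(rnorm(n * B), nrow = n)
  Y <- matrix(rnorm(n * B), nrow = n)
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  stat <- abs(colSums(Xc * Yc) / sqrt(colSums(Xc^2) * colSums(Yc^2)))
  mean(stat >= abs(r_obs))
}

# Surgeon x exercise table whose group means are (almost) exactly the
# requested values, so equation-level pipelines can be hand-checked.
make_metric_table <- function(per_exercise_means, n_per_group = 6, sd = 1e-6,
                              metrics = names(per_exercise_means[[1]][[1]])) {
  # builds a surgeon x exercise table whose group means are (almost) exactly
  # the requested values, so the Eq-level pipeline can be hand-checked
  rows <- list()
  set.seed(1)
  for (ex in names(per_exercise_means)) {
    for (g in names(per_exercise_means[[ex]])) {
      for (s in seq_len(n_per_group)) {
        vals <- per_exercise_means[[ex]][[g]]
        row <- tibble::as_tibble(as.list(vals + rnorm(length(vals), sd = sd)))
        row$surgeon_id <- paste0(g, s)
        row$group <- g
        row$exercise_id <- ex
        rows[[length(rows) + 1]] <- row
      }
    }
  }
  dplyr::bind_rows(rows)
}
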