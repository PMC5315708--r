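fixture_episodes <- tibble::tibble(start = c(1, 4, 9), end = c(2, 6, 9.5))

test_that("camera metrics match hand arithmetic on the canonical fixture", {
  expect_equal(camera_movement_frequency(fixture_episodes, 10), 0.3)
  expect_equal(camera_movement_duration(fixture_episodes), 7 / 6)
  expect_equal(camera_movement_interval(fixture_episodes), 2.5)

  expect_equal(camera_movement_frequency(fixture_episodes[0, ], 60), 0)
  expect_equal(camera_movement_duration(tibble::tibble(start = 0, end = 0.8)), 0.8)
  expect_true(is.na(camera_movement_duration(fixture_episodes[0, ])))
  expect_true(is.na(camera_movement_interval(fixture_episodes[1, ])))
  # abutting episodes have zero gap
  expect_equal(camera_movement_interval(tibble::tibble(start = c(0, 1), end = c(1, 2))), 0)
  # start-to-start convention measures the period instead
  expect_equal(
    camera_movement_interval(fixture_episodes, convention = "start_to_start"), 4
  )
  expect_error(camera_movement_frequency(fixture_episodes, 0),
               class = "scopemetrics_domain_error")
})

test_that("completion time is the sample span, ignoring the start offset", {
  expect_equal(completion_time(make_trial(t = seq(0, 212.4, length.out = 100))), 212.4)
  expect_equal(completion_time(make_trial(t = seq(5, 15, by = 0.5))), 10)
})

test_that("economy of motion is the summed instrument polyline length", {
  # straight line: 0.3 m regardless of sampling
  t <- seq(0, 3, by = 0.1)
  line <- cbind(0, 0, seq(0, 0.3, length.out = length(t)))
  tr <- make_trial(t = t, instruments = list(line))
  expect_equal(economy_of_motion(tr), 0.3)

  # two instruments tracing the same path: additive
  tr2 <- make_trial(t = t, instruments = list(line, line))
  expect_equal(economy_of_motion(tr2), 0.6)

  # circle sampled at 1 degree steps: chord-sum closed form 360 * 2 * sin(pi/360)
  theta <- seq(0, 2 * pi, length.out = 361)
  circ <- cbind(cos(theta), sin(theta), 0)
  tr3 <- make_trial(t = seq_along(theta) - 1, sample_rate = 1,
                    instruments = list(circ))
  expect_equal(economy_of_motion(tr3), 360 * 2 * sin(pi / 360), tolerance = 1e-12)
})

test_that("master workspace range matches closed forms and a sort oracle", {
  # both hands stationary
  expect_equal(master_workspace_range(make_trial()), 0)

  # left hand alternating between (+-0.1, 0, 0): centroid at origin, r = 0.1
  n <- 100
  t <- seq(0, by = 0.02, length.out = n)
  left <- cbind(rep(c(0.1, -0.1), n / 2), 0, 0)
  tr <- make_trial(t = t, left = left)
  expect_equal(master_workspace_range(tr, "scaled_max"), 0.085)

  # antipodal point pairs on a radius-0.2 sphere: centroid is the center
  # exactly, every distance is 0.2, so scaled_max gives 0.17 exactly
  set.seed(11)
  m <- 500
  u <- matrix(rnorm(3 * m), ncol = 3)
  u <- 0.2 * u / sqrt(rowSums(u^2))
  sphere <- rbind(u, -u)
  tr2 <- make_trial(t = seq(0, by = 0.02, length.out = 2 * m), left = sphere)
  expect_equal(master_workspace_range(tr2, "scaled_max"), 0.17)

  # percentile mode against a brute-force distance computation
  set.seed(12)
  cloud <- matrix(rnorm(3 * 200, sd = 0.05), ncol = 3)
  tr3 <- make_trial(t = seq(0, by = 0.02, length.out = 200), left = cloud)
  d_left <- sqrt(rowSums(sweep(cloud, 2, colMeans(cloud))^2))
  d_right <- 0 # right hand fixed
  expect_equal(master_workspace_range(tr3, "percentile"),
               max(quantile(d_left, 0.85), d_right), ignore_attr = TRUE)
})

test_that("compute_metric_set composes the parts and keeps its invariant", {
  tr <- make_trial(t = seq(0, 10, by = 0.02), events = camera_events(fixture_episodes))
  ms <- compute_metric_set(tr)
  expect_equal(ms$cfrq, 0.3)
  expect_equal(ms$cdur, 7 / 6)
  expect_equal(ms$cint, 2.5)
  expect_equal(ms$comp_time, 10)
  expect_equal(ms$n_episodes, 3)
  expect_true(is.na(ms$overall_score))

  # zero-episode trial: cfrq 0, cdur/cint missing
  ms0 <- compute_metric_set(make_trial(t = seq(0, 10, by = 0.02)))
  expect_equal(ms0$cfrq, 0)
  expect_true(is.na(ms0$cdur))
  expect_true(is.na(ms0$cint))

  # randomized trials: cfrq equals n_episodes / comp_time
  for (seed in 1:5) {
    tr <- generate_trial(default_profiles(1)$intermediate, "S01", "EX1",
                         sample_rate = 10, seed = seed)
    ms <- compute_metric_set(tr)
    expect_equal(ms$cfrq, ms$n_episodes / ms$comp_time)
    if (ms$n_episodes >= 1) {
      expect_lte(ms$cdur * ms$n_episodes, ms$comp_time)
    }
  }
})

test_that("time rescaling and rigid translation transform metrics as expected", {
  set.seed(21)
  n <- 201
  t <- seq(0, 10, length.out = n)
  inst <- cbind(cumsum(rnorm(n, sd = 1e-3)), cumsum(rnorm(n, sd = 1e-3)), 0.05)
  ep <- tibble::tibble(start = c(1, 5), end = c(2, 7))
  tr <- make_trial(t = t, instruments = list(inst), events = camera_events(ep))
  base <- compute_metric_set(tr)

  # t -> k t scales the time metrics by k and divides cfrq by k
  k <- 2.5
  trk <- make_trial(t = k * t, instruments = list(inst),
                    events = camera_events(ep * k))
  scaled <- compute_metric_set(trk)
  expect_equal(scaled$comp_time, k * base$comp_time)
  expect_equal(scaled$cdur, k * base$cdur)
  expect_equal(scaled$cint, k * base$cint)
  expect_equal(scaled$cfrq, base$cfrq / k)
  expect_equal(scaled$eom, base$eom)
  expect_equal(scaled$mwr, base$mwr)

  # rigid translation of all positions leaves eom and mwr unchanged
  shift <- c(0.3, -0.2, 1)
  trs <- make_trial(
    t = t,
    left = matrix(rep(c(-0.1, 0, 0) + shift, each = n), ncol = 3),
    right = matrix(rep(c(0.1, 0, 0) + shift, each = n), ncol = 3),
    instruments = list(sweep(inst, 2, shift, `+`)),
    events = camera_events(ep)
  )
  moved <- compute_metric_set(trs)
  expect_equal(moved$eom, base$eom)
  expect_equal(moved$mwr, base$mwr)
})

test_that("off-path samples never decrease the instrument path length", {
  t <- c(0, 1, 2)
  straight <- cbind(c(0, 0.1, 0.2), 0, 0)
  base <- economy_of_motion(make_trial(t = t, instruments = list(straight)))

  # collinear refinement preserves length
  t4 <- c(0, 0.5, 1, 2)
  collinear <- cbind(c(0, 0.05, 0.1, 0.2), 0, 0)
  expect_equal(economy_of_motion(make_trial(t = t4, instruments = list(collinear))), base)

  # any off-path insertion increases it
  for (seed in 1:10) {
    set.seed(seed)
    off <- cbind(c(0, 0.05, 0.1, 0.2), c(0, runif(1, 0.001, 0.05), 0, 0), 0)
    expect_gt(economy_of_motion(make_trial(t = t4, instruments = list(off))), base)
  }
})
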