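test_that("pooled Student t matches the hand-computed formula", {
  res <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  # means 2 and 5, pooled variance 1, se = sqrt(2/3)
  expect_equal(res$t, -3 / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(res$t, -3.674, tolerance = 1e-3)
  expect_equal(res$df, 4)
  expect_equal(res$p, 2 * pt(-3 / sqrt(2 / 3), 4))
  expect_equal(res$p, 0.0213, tolerance = 1e-3)

  # identical samples: no difference
  res2 <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res2$t, 0)
  expect_equal(res2$p, 1)

  # degenerate: zero pooled variance is flagged, not raised
  res3 <- two_sample_t(c(0, 0), c(0, 0))
  expect_false(res3$computable)
  expect_true(is.na(res3$p))

  # too-small samples flagged; NAs dropped first
  expect_false(two_sample_t(c(1, NA), c(2, 3))$computable)
  expect_equal(two_sample_t(c(1, 2, 3, NA), c(4, 5, 6))$df, 4)

  # Welch variant reproduces stats::t.test
  a <- c(1, 5, 9, 2); b <- c(2, 2.5, 3)
  expect_equal(two_sample_t(a, b, "welch")$p, t.test(a, b)$p.value)
})

test_that("Pearson correlation and its t-based p match closed forms", {
  x <- c(1, 2, 3, 4, 5)
  y <- 2 * x + 1
  res <- pearson_with_p(x, y)
  expect_equal(res$r, 1)
  expect_lt(res$p, 1e-10)
  expect_equal(pearson_with_p(x, -x)$r, -1)

  y2 <- c(2, 1, 4, 3, 6)
  res2 <- pearson_with_p(x, y2)
  r_hand <- sum((x - mean(x)) * (y2 - mean(y2))) /
    sqrt(sum((x - mean(x))^2) * sum((y2 - mean(y2))^2))
  expect_equal(res2$r, r_hand)
  expect_equal(res2$r, 0.8220, tolerance = 1e-4)
  t_hand <- r_hand * sqrt((5 - 2) / (1 - r_hand^2))
  expect_equal(res2$p, 2 * pt(-abs(t_hand), 3))

  # zero variance flagged
  expect_false(pearson_with_p(rep(1, 5), 1:5)$computable)
  expect_false(pearson_with_p(1:2, 2:1)$computable)
})

test_that("analytic p-values agree with permutation oracles at a finite-sample tolerance", {
  # The randomization distribution differs from the t reference by O(1/n),
  # so small-n agreement is approximate, not at Monte-Carlo resolution.
  set.seed(31)
  for (i in 1:5) {
    a <- rnorm(10); b <- rnorm(10)
    p_t <- two_sample_t(a, b)$p
    p_perm <- perm_p_two_sample(a, b, B = 2e4)
    expect_lt(abs(p_t - p_perm), 0.05)

    x <- rnorm(10); y <- rnorm(10)
    p_r <- pearson_with_p(x, y)$p
    expect_lt(abs(p_r - perm_p_cor(x, y, B = 2e4)), 0.05)
  }
})

test_that("min-max normalization maps onto [0, 1] and flags degeneracy", {
  nm <- minmax_normalize(c(2, 4, 6))
  expect_equal(nm$values, c(0, 0.5, 1))
  expect_equal(nm$x_min, 2)
  expect_equal(nm$x_max, 6)
  expect_false(nm$degenerate)

  flat <- minmax_normalize(c(3, 3, 3))
  expect_equal(flat$values, c(0, 0, 0))
  expect_true(flat$degenerate)

  for (seed in 1:10) {
    set.seed(seed)
    v <- minmax_normalize(rnorm(7))$values
    expect_equal(min(v), 0)
    expect_equal(max(v), 1)
    expect_true(all(v >= 0 & v <= 1))
  }
  expect_error(minmax_normalize(3), class = "scopemetrics_domain_error")
})

test_that("the normalization/discrimination pipeline reproduces the worked example", {
  # 3 exercises; metric A group means: new {1,2,3}, experienced {3,4,5}
  tbl <- make_metric_table(list(
    E1 = list(new = c(m = 1), experienced = c(m = 3)),
    E2 = list(new = c(m = 2), experienced = c(m = 4)),
    E3 = list(new = c(m = 3), experienced = c(m = 5))
  ))
  disc <- discrimination(tbl, metrics = "m")
  expect_equal(disc$ranking$d, 0.5, tolerance = 1e-4)
  # shared min/max: normalized new {0, .25, .5}, experienced {.5, .75, 1}
  expect_equal(sort(disc$per_exercise$m), rep(0.5, 3), tolerance = 1e-4)
})

test_that("discrimination ranks, flags ties, and respects invariances", {
  tbl <- make_metric_table(list(
    E1 = list(new = c(strong = 1, none = 5, twin = 1), experienced = c(strong = 9, none = 5, twin = 1)),
    E2 = list(new = c(strong = 2, none = 7, twin = 2), experienced = c(strong = 10, none = 7, twin = 2)),
    E3 = list(new = c(strong = 3, none = 6, twin = 3), experienced = c(strong = 11, none = 6, twin = 3))
  ))
  disc <- discrimination(tbl, metrics = c("strong", "none", "twin"))
  expect_equal(disc$ranking$metric[1], "strong")
  # metrics on which the groups coincide rank last with d ~ 0
  expect_lt(disc$ranking$d[disc$ranking$metric == "none"], 1e-3)

  # identical per-exercise means for two metrics: equal d, pairwise p = 1
  tbl2 <- make_metric_table(list(
    E1 = list(new = c(a = 1, b = 1), experienced = c(a = 3, b = 3)),
    E2 = list(new = c(a = 2, b = 2), experienced = c(a = 5, b = 5)),
    E3 = list(new = c(a = 4, b = 4), experienced = c(a = 6, b = 6))
  ), sd = 0)
  disc2 <- discrimination(tbl2, metrics = c("a", "b"))
  expect_equal(disc2$ranking$d[1], disc2$ranking$d[2])
  expect_equal(disc2$pairwise_p["a", "b"], 1)

  # exercise order permutation leaves the ranking unchanged
  tbl_perm <- tbl[order(tbl$exercise_id, decreasing = TRUE), ]
  disc_perm <- discrimination(tbl_perm, metrics = c("strong", "none", "twin"))
  expect_equal(disc_perm$ranking$d, disc$ranking$d)

  # affine rescaling of a metric's raw units is absorbed by normalization
  tbl_aff <- tbl
  tbl_aff$strong <- 100 * tbl_aff$strong - 7
  disc_aff <- discrimination(tbl_aff, metrics = c("strong", "none", "twin"))
  expect_equal(disc_aff$ranking$d, disc$ranking$d, tolerance = 1e-9)

  expect_error(discrimination(tbl[tbl$exercise_id == "E1", ], metrics = "strong"),
               class = "scopemetrics_domain_error")
})

test_that("group comparisons report per-group stats and flag absent groups", {
  spec <- cohort_spec("EX1", seed = 8, sample_rate = 2,
                      group_sizes = c(new = 6L, intermediate = 4L, experienced = 6L))
  tbl <- simulate_metrics(spec, add_score = FALSE)
  gc <- group_comparisons(tbl, "comp_time", "EX1")
  expect_equal(gc$n_new, 6)
  expect_equal(gc$n_int, 4)
  expect_equal(gc$mean_new, mean(tbl$comp_time[tbl$group == "new"]))
  expect_equal(gc$sd_exp, sd(tbl$comp_time[tbl$group == "experienced"]))
  expect_true(all(c(gc$p_new_vs_int, gc$p_new_vs_exp, gc$p_int_vs_exp) >= 0 &
                    c(gc$p_new_vs_int, gc$p_new_vs_exp, gc$p_int_vs_exp) <= 1,
                  na.rm = TRUE))

  # a group reduced to one surgeon yields flagged (missing) p-values
  one_int <- tbl$surgeon_id[tbl$group == "intermediate"][1]
  tbl1 <- tbl[tbl$group != "intermediate" | tbl$surgeon_id == one_int, ]
  gc1 <- group_comparisons(tbl1, "comp_time", "EX1")
  expect_true(is.na(gc1$p_new_vs_int))
  expect_true(is.na(gc1$p_int_vs_exp))
  expect_false(is.na(gc1$p_new_vs_exp))

  expect_error(group_comparisons(tbl, "comp_time", "EX99"),
               class = "scopemetrics_domain_error")
})

test_that("camera metrics correlate with raw completion time in the expected direction", {
  # skill drives camera frequency up and completion time down, so pooled
  # correlations should come out negative for cfrq and positive for cdur
  hits_cfrq <- 0
  for (seed in 1:20) {
    spec <- cohort_spec("EX1", seed = seed, sample_rate = 2)
    tbl <- simulate_metrics(spec)
    corr <- metric_target_correlations(tbl)
    r <- corr$r[corr$metric == "cfrq" & corr$target == "comp_time"]
    if (is.finite(r) && r < 0) hits_cfrq <- hits_cfrq + 1
  }
  expect_gte(hits_cfrq, 19)
})

test_that("correlation bookkeeping covers exercises x metrics x targets", {
  spec <- cohort_spec(c("A", "B"), seed = 4, sample_rate = 2,
                      group_sizes = c(new = 4L, intermediate = 2L, experienced = 4L))
  tbl <- simulate_metrics(spec)
  corr <- metric_target_correlations(tbl)
  expect_equal(nrow(corr), 2 * 3 * 2)

  # constant target flagged
  tbl$overall_score <- 50
  corr2 <- metric_target_correlations(tbl)
  expect_true(all(!corr2$computable[corr2$target == "overall_score"]))
})

test_that("validity tables carry the table-per-metric shape and flags", {
  spec <- cohort_spec(c("A", "B"), seed = 12, sample_rate = 2,
                      group_sizes = c(new = 5L, intermediate = 3L, experienced = 5L))
  tbl <- simulate_metrics(spec)
  tabs <- validity_tables(tbl)
  expect_named(tabs, c("cfrq", "cdur", "cint"))
  expect_equal(nrow(tabs$cfrq), 2)
  expect_true(all(c("mean_new", "sd_new", "p_new_vs_int", "p_new_vs_exp",
                    "p_int_vs_exp", "r_time", "p_time", "r_score", "p_score",
                    "sig_new_vs_exp") %in% names(tabs$cfrq)))
  expect_equal(attr(tabs, "n_comparisons"), 3 * 2 * 5)

  # flags follow the threshold; values do not change with it
  tabs01 <- validity_tables(tbl, alpha = 0.01)
  expect_equal(tabs01$cfrq$p_new_vs_exp, tabs$cfrq$p_new_vs_exp)
  expect_true(all(tabs01$cfrq$sig_new_vs_exp <= tabs$cfrq$sig_new_vs_exp))
})
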