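test_that("percent change reproduces published worked examples", {
  expect_equal(round(percent_change(1071, 1186), 1), 10.7)
  expect_equal(round(percent_change(96, 108), 1), 12.5)
  expect_equal(percent_change(1500, 1500), 0)
  expect_error(percent_change(0, 10), "non-zero")
})

test_that("bias-corrected Hedge's g reproduces published worked examples", {
  expect_equal(round(hedges_g(1071, 250, 1186, 246, 14), 2), 0.45)
  expect_equal(round(hedges_g(291.2, 111.4, 456.4, 171.9, 14), 2), 1.11)
  expect_equal(hedges_g(100, 10, 100, 12, 14), 0)
  expect_error(hedges_g(1, 0, 1, 0, 14), "pooled SD")
})

test_that("the effect-size confidence interval matches published intervals", {
  g1 <- hedges_g(1071, 250, 1186, 246, 14)
  ci1 <- hedges_ci(g1, 14)
  expect_equal(round(ci1$ci_low, 2), -0.30)
  expect_equal(round(ci1$ci_high, 2), 1.20)

  g2 <- hedges_g(291.2, 111.4, 456.4, 171.9, 14)
  ci2 <- hedges_ci(g2, 14)
  expect_equal(round(ci2$ci_low, 2), 0.31)
  expect_equal(round(ci2$ci_high, 2), 1.90)

  # null effect, large n: interval shrinks towards zero
  wide <- hedges_ci(0, 14)
  narrow <- hedges_ci(0, 10000)
  expect_lt(narrow$ci_high, 0.05)
  expect_lt(narrow$ci_high, wide$ci_high)
})

test_that("magnitude labels respect the half-open bins", {
  expect_equal(label_effect(c(0, 0.19, 0.2, 0.45, 0.6, 1.11, 1.2, 2, 4, 5)),
               c("trivial", "trivial", "small", "small", "moderate",
                 "moderate", "large", "very large", "extremely large",
                 "extremely large"))
  expect_equal(label_effect(-0.45), "small")
  expect_equal(label_correlation(c(0.05, 0.1, 0.3, 0.5, 0.7, 0.9, 1, -0.95)),
               c("trivial", "small", "moderate", "large", "very large",
                 "almost perfect", "almost perfect", "almost perfect"))
})

test_that("pearson correlation matches a from-definition oracle", {
  x <- 1:10
  perfect <- pearson_corr(x, 2 * x + 1)
  expect_equal(perfect$r, 1, tolerance = 1e-12)
  expect_equal(perfect$label, "almost perfect")

  orth <- pearson_corr(c(1, 2, 3, 4), c(1, -1, -1, 1))
  expect_equal(orth$r, 0, tolerance = 1e-12)

  set.seed(11)
  for (i in 1:100) {
    a <- rnorm(8)
    b <- rnorm(8)
    expect_equal(pearson_corr(a, b)$r, oracle_pearson_r(a, b),
                 tolerance = 1e-12)
  }
  expect_error(pearson_corr(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(pearson_corr(1:4, 1:5), "equal length")
})

test_that("paired comparison behaves correctly at the edges and under the null", {
  expect_error(paired_comparison(1:5, 1:5 + 5), "zero variance")
  expect_error(paired_comparison(1:4, 1:5), "equal length")
  res <- paired_comparison(c(10, 12, 14, 16), c(12, 13, 17, 18))
  expect_equal(res$mean_diff, 2)

  rejections <- vapply(1:200, function(s) {
    set.seed(s)
    pre <- rnorm(12, 100, 10)
    post <- rnorm(12, 100, 10)
    paired_comparison(pre, post)$p < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.005)
  expect_lt(mean(rejections), 0.11)
})

test_that("effect sizes are sign-symmetric and scale-invariant", {
  g <- hedges_g(100, 15, 120, 18, 14)
  g_swapped <- hedges_g(120, 18, 100, 15, 14)
  expect_equal(g_swapped, -g, tolerance = 1e-12)

  g_scaled <- hedges_g(100 * 3.7, 15 * 3.7, 120 * 3.7, 18 * 3.7, 14)
  expect_equal(g_scaled, g, tolerance = 1e-12)
  expect_equal(percent_change(100 * 3.7, 120 * 3.7), percent_change(100, 120),
               tolerance = 1e-12)

  set.seed(3)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(pearson_corr(5 * x, 5 * y)$r, pearson_corr(x, y)$r,
               tolerance = 1e-12)
  expect_equal(pearson_corr(5 * x, 5 * y)$p, pearson_corr(x, y)$p,
               tolerance = 1e-12)
})

test_that("change correlations recover a built-in delta correlation", {
  metrics <- tibble::tibble(
    metric = c("a", "b"),
    pre_mean = c(100, 200), pre_sd = c(2, 4),
    change = c(10, 20), change_sd = c(5, 10))
  rho <- matrix(c(1, 0.9, 0.9, 1), 2)
  spec <- cohort_spec(n_participants = 200, metrics = metrics,
                      pairing = "additive", change_cor = rho)
  cohort <- generate_cohort(spec, seed = 9)
  cc <- change_correlation_matrix(cohort$table, predictors = "a",
                                  outcomes = "b")
  expect_equal(cc$r, 0.9, tolerance = 0.05)

  # independent changes: correlation centred on zero
  spec0 <- cohort_spec(n_participants = 200, metrics = metrics,
                       pairing = "additive")
  cohort0 <- generate_cohort(spec0, seed = 9)
  cc0 <- change_correlation_matrix(cohort0$table, predictors = "a",
                                   outcomes = "b")
  expect_lt(abs(cc0$r), 0.2)

  # too few complete pairs is an error
  tiny <- cohort$table[cohort$table$participant %in% c("P01", "P02"), ]
  expect_error(change_correlation_matrix(tiny, "a", "b"), "n >= 3")
})

test_that("participants missing a timepoint are dropped with a warning", {
  metrics <- tibble::tibble(metric = "a", pre_mean = 100, pre_sd = 5,
                            change = 10)
  cohort <- generate_cohort(cohort_spec(n_participants = 10,
                                        metrics = metrics), seed = 1)
  tbl <- cohort$table
  tbl <- tbl[!(tbl$participant == "P01" & tbl$timepoint == "post"), ]
  expect_warning(out <- build_summary_table(tbl), "dropping 1")
  expect_equal(out$n, 9)
})

test_that("the summary table reproduces the published rows it is fed", {
  ref <- reference_training_summary()
  out <- summary_effects(ref, n = 14)
  consistent <- ref$pct_consistent
  expect_equal(round(out$pct_change[consistent], 1),
               ref$pct_change_printed[consistent])
  gc <- ref$g_consistent
  expect_equal(round(out$g[gc], 2), ref$g_printed[gc])
  expect_equal(round(out$ci_low[gc], 2), ref$ci_low_printed[gc])
  expect_equal(round(out$ci_high[gc], 2), ref$ci_high_printed[gc])
  expect_equal(out$label[out$metric == "ppo_w"], "small")
  expect_equal(out$label[out$metric == "rtd_0_100"], "moderate")
})
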