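test_that("spearman correlation handles monotone, tied and degenerate data", {
  r <- spearman_cor(1:4, c(10, 20, 30, 40))
  expect_equal(r$rho, 1)
  expect_equal(spearman_cor(1:4, c(40, 30, 20, 10))$rho, -1)

  # invariance under strictly monotone transforms
  set.seed(4)
  x <- rnorm(30); y <- x + rnorm(30)
  expect_equal(spearman_cor(x, y)$rho, spearman_cor(exp(x), y^3)$rho)

  d <- spearman_cor(1:3, c(2, 2, 2))
  expect_equal(d$rho, 0)
  expect_true(d$degenerate)

  expect_error(spearman_cor(1:2, 1:2), ">= 3")
})

test_that("group comparison routes by Shapiro-Wilk normality", {
  set.seed(3)
  base <- rnorm(20)
  same <- compare_groups(c(base, base), rep(c("a", "b"), each = 20))
  expect_equal(same$method, "anova_tukey")
  expect_gt(same$omnibus$p_value, 0.99)
  expect_true(all(same$pairwise$p_adj > 0.99))

  set.seed(10)
  sep <- compare_groups(c(rnorm(20), rnorm(20, 5)),
                        rep(c("lo", "hi"), each = 20))
  expect_lt(sep$omnibus$p_value, 0.001)
  expect_true(all(sep$pairwise$p_adj >= 0 & sep$pairwise$p_adj <= 1))

  set.seed(42)
  ex <- compare_groups(c(rexp(50), rexp(50, 0.2), rexp(50, 3)),
                       rep(1:3, each = 50))
  expect_equal(ex$method, "kruskal_dunn")
  expect_equal(nrow(ex$pairwise), 3L)  # all group pairs covered
  expect_true(all(ex$pairwise$p_adj >= 0 & ex$pairwise$p_adj <= 1))

  expect_warning(
    two <- compare_groups(c(rnorm(10), rnorm(10, 3), 1, 2),
                          rep(c("a", "b", "c"), c(10, 10, 2))),
    "n < 3")
  expect_error(
    suppressWarnings(compare_groups(c(1, 2, 1:3), rep(c("a", "b"), c(2, 3)))),
    "fewer than 2")
})

test_that("Dunn adjusted p-values dominate the raw ones", {
  set.seed(9)
  v <- c(rexp(15), rexp(15, 0.5), rexp(15, 2))
  g <- factor(rep(1:3, each = 15))
  dn <- fibrofractal:::dunn_posthoc(v, g)
  expect_true(all(dn$p_adj >= dn$p_raw))
  expect_true(all(dn$p_adj <= 1))
})

test_that("margin/focus comparison produces per-patient deltas", {
  tbl <- data.frame(
    patient_id = rep(sprintf("P%d", 1:6), each = 2),
    location = rep(c("margin", "focus"), 6),
    fibrosis_score = rep(c(0, 4), 6),
    fd = rep(1:6, each = 2) / 10 + rep(c(0, 1), 6))
  res <- compare_two_paired_locations(tbl, "fd")
  expect_equal(res$deltas$delta, rep(1, 6))  # focus = margin + 1
  expect_equal(nrow(res$deltas), 6L)

  # a patient missing its focus record is excluded with a warning
  tbl2 <- tbl[-2, ]
  expect_warning(res2 <- compare_two_paired_locations(tbl2, "fd"),
                 "excluded")
  expect_equal(nrow(res2$deltas), 5L)

  expect_error(compare_two_paired_locations(tbl, "nope"), "not present")
})

test_that("discrimination check demands strictly positive deltas", {
  expect_true(discrimination_check(c(0.01, 0.2))$discriminates)
  r <- discrimination_check(c(0.5, -0.01, 0.3))
  expect_false(r$discriminates)
  expect_equal(r$violations, 1L)
  expect_equal(discrimination_check(c(0.1, 0))$violations, 1L)  # tie
  expect_error(discrimination_check(numeric(0)), "no paired")
})

test_that("relative expression and collagen ratio follow the delta-CT rules", {
  expect_equal(relative_expression(20, 20), 1)
  expect_equal(relative_expression(21, 20), 0.5)
  expect_equal(relative_expression(18, 20), 4)
  expect_error(relative_expression(NA, 20), "non-finite")

  expect_equal(collagen_ratio(0.45, 0.37), 0.45 / 0.37)
  expect_error(collagen_ratio(0.45, 0), "non-zero")
})

test_that("the cohort report reproduces the expected effect directions", {
  tb <- simulate_cohort(seed = 1)
  rep <- stats_report(tb)
  expect_equal(rep$n_patients, 28L)
  expect_equal(rep$n_records, 56L)
  cors <- rep$correlations
  expect_gt(cors$fibrosis_score_vs_fractal_dimension$rho, 0)
  expect_lt(cors$fibrosis_score_vs_lacunarity$rho, 0)
  expect_lt(cors$fractal_dimension_vs_lacunarity$rho, 0)

  # fractal dimension discriminates focus from margin per patient
  expect_true(rep$location_comparisons$fractal_dimension$discriminates)

  # serializes to JSON without error
  expect_silent(jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA,
                                 force = TRUE))
})
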