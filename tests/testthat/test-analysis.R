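# exhaustive Mann-Whitney U oracle: count pairs (x > y) + half-ties
oracle_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) u <- u + (xi > yj) + 0.5 * (xi == yj)
  u
}

test_that("brain age gap is the signed difference", {
  expect_equal(compute_gap(12, 10), 2)
  expect_equal(compute_gap(10, 10), 0)
  expect_equal(compute_gap(8.5, 10), -1.5)
  expect_equal(compute_gap(10, 12), -compute_gap(12, 10))
})

test_that("MAE and IQR follow the linear-interpolation percentile convention", {
  expect_equal(mae_iqr(gap = c(1, -2, 3))$mae, 2)
  z <- mae_iqr(gap = rep(0, 5))
  expect_equal(c(z$mae, z$iqr_lo, z$iqr_hi), c(0, 0, 0))
  set.seed(12)
  g <- rnorm(37)
  got <- mae_iqr(gap = g)
  ae <- sort(abs(g)); n <- length(ae)
  interp <- function(p) {
    h <- (n - 1) * p + 1
    ae[floor(h)] + (h - floor(h)) * (ae[ceiling(h)] - ae[floor(h)])
  }
  expect_lt(abs(got$iqr_lo - interp(0.25)), 1e-9)
  expect_lt(abs(got$iqr_hi - interp(0.75)), 1e-9)
  df <- tibble::tibble(predicted_age = c(11, 13), age = c(10, 10))
  expect_equal(mae_iqr(df)$mae, 2)
  expect_error(mae_iqr(gap = numeric(0)), "no records")
})

test_that("outlier grouping is stratified, order-invariant, and SD-thresholded", {
  df <- tibble::tibble(age = rep(10.2, 5), sex = "F",
                       predicted_age = c(10, 10, 10, 10, 20))
  got <- classify_gap_outliers(df)
  expect_equal(got$group, c(rep("Average", 4), "Older"))
  same <- tibble::tibble(age = rep(12.7, 4), sex = "M", predicted_age = rep(9, 4))
  expect_true(all(classify_gap_outliers(same)$group == "Average"))
  # order invariance
  set.seed(13)
  big <- tibble::tibble(age = runif(300, 8, 12), sex = sample(c("F", "M"), 300, TRUE),
                        predicted_age = rnorm(300, 10))
  perm <- sample(300)
  g1 <- classify_gap_outliers(big)$group
  g2 <- classify_gap_outliers(big[perm, ])$group
  expect_identical(g1[perm], g2)
  expect_warning(classify_gap_outliers(
    tibble::tibble(age = c(5.1, 5.2), sex = "F", predicted_age = c(5, 6))),
    "Average")
  # under a Gaussian null the non-Average fraction approaches 2 * pnorm(-1)
  null_df <- withr::with_seed(14, tibble::tibble(
    age = rep(10.5, 1e4), sex = "F", predicted_age = rnorm(1e4)))
  frac <- mean(classify_gap_outliers(null_df)$group != "Average")
  expect_lt(abs(frac - 2 * pnorm(-1)), 0.02)
})

test_that("group comparisons match the exhaustive U oracle and Bonferroni design", {
  set.seed(15)
  # U equals exhaustive enumeration for all group sizes <= 8
  for (nx in c(2, 5, 8)) for (ny in c(2, 5, 8)) {
    x <- sample(1:10, nx, TRUE); y <- sample(1:10, ny, TRUE)
    wt <- suppressWarnings(wilcox.test(x, y))
    expect_equal(unname(wt$statistic), oracle_u(x, y))
  }
  tab <- generate_volumetric_table(60, effect = list(), seed = 16)
  tab$group <- tab$planted_group
  res <- group_compare(tab)
  expect_equal(nrow(res), 16)  # 4 measures x 2 sexes x 2 pairs
  expect_equal(unique(res$alpha_adjusted), 0.05 / 16)
  # identical groups: d = 0 and no significance
  ident <- tibble::tibble(sex = "F", group = rep(c("Older", "Average"), each = 6),
                          WMV = rep(c(5, 6, 7), 4), GMV = 1, sGMV = 1, VV = 1)
  ri <- group_compare(ident, measures = "WMV")
  expect_equal(ri$cohens_d, 0)
  expect_gt(ri$p_value, 0.05 / 16)
  # planted shift is detected
  shifted <- generate_volumetric_table(400, effect = list(Older = c(VV = 1)),
                                       seed = 17)
  shifted$group <- shifted$planted_group
  rs <- group_compare(shifted)
  expect_true(all(rs$significant[rs$measure == "VV" & rs$group == "Older"]))
})

test_that("longitudinal rates and categories follow the cohort-SD rule", {
  flat <- tidyr::expand_grid(subject_id = sprintf("F%02d", 1:5), visit = 1:3) |>
    dplyr::mutate(age = 10 + 2 * (visit - 1), predicted_age = age - 0.5,
                  WMV = 100 + 6 * age, GMV = 700 - 5 * age,
                  sGMV = 60 - 0.3 * age, VV = 10 + 0.6 * age)
  got <- categorize_longitudinal(flat)
  expect_true(all(got$subjects$category == "Stable"))
  # hand-built 3-visit subject: interval rates 5 and 8 per year
  hand <- tibble::tibble(subject_id = "A", visit = 1:3, age = c(10, 12, 14),
                         predicted_age = c(10, 12, 14),
                         WMV = c(100, 110, 126), GMV = 1, sGMV = 1, VV = 1)
  rates <- diffage:::subject_rates(hand, c("WMV", "GMV", "sGMV", "VV"))
  expect_equal(rates$rate_WMV, mean(c(5, 8)))
  expect_equal(rates$brainage_rate, 1)
  # planted accelerated subgroup is recovered and associated with VV growth
  planted <- generate_longitudinal_cohort(200, seed = 19,
                                          accelerated_fraction = 0.15)
  res <- categorize_longitudinal(planted)
  truth <- dplyr::distinct(planted, subject_id, planted_group)
  joined <- dplyr::left_join(res$subjects, truth, by = "subject_id")
  sens <- mean(joined$category[joined$planted_group == "Accelerated"] ==
                 "Accelerated")
  expect_gt(sens, 0.9)
  expect_equal(unique(res$comparisons$alpha_adjusted), 0.05 / 8)
  expect_true(any(res$comparisons$significant[res$comparisons$measure == "VV"]))
  expect_error(categorize_longitudinal(hand[1, ]), ">= 2")
})

test_that("R-squared comparison matches the closed form", {
  set.seed(20)
  n <- 200
  df <- generate_volumetric_table(n, seed = 21)[1:n, ]
  df$predicted_age <- df$age + rnorm(n, sd = 0.5)
  got <- compare_age_models(df)
  expect_equal(got$outcome, c("chronological_age", "brain_age"))
  # closed-form oracle: 1 - SSR/SST
  X <- model.matrix(~ WMV + GMV + sGMV + VV + sex, df)
  for (i in 1:2) {
    yv <- if (i == 1) df$age else df$predicted_age
    bet <- solve(crossprod(X), crossprod(X, yv))
    r2 <- 1 - sum((yv - X %*% bet)^2) / sum((yv - mean(yv))^2)
    expect_lt(abs(got$r_squared[i] - r2), 1e-9)
  }
  # exact linear outcome gives R^2 = 1; pure noise stays near 0
  df$predicted_age <- 2 * df$WMV - 0.5 * df$GMV + 3 * (df$sex == "M")
  # exact fit triggers the usual "essentially perfect fit" note from lm
  expect_equal(suppressWarnings(compare_age_models(df)$r_squared[2]), 1)
  big <- generate_volumetric_table(340, seed = 22)[1:1000, ]
  big$predicted_age <- rnorm(1000)
  expect_lt(compare_age_models(big)$r_squared[2], 0.02)
  expect_error(compare_age_models(df[1:5, ]), ">= 10")
})

test_that("age-bias correction recovers planted bias and centres residuals", {
  set.seed(23)
  n <- 500
  fit_df <- tibble::tibble(age = runif(n, 5, 25))
  fit_df$predicted_age <- fit_df$age - 0.5 * (fit_df$age - 15) + rnorm(n, sd = 0.4)
  app <- tibble::tibble(age = runif(n, 5, 25))
  app$predicted_age <- app$age - 0.5 * (app$age - 15) + rnorm(n, sd = 0.4)
  out <- age_bias_correct(app, fit_df)
  expect_lt(abs(attr(out, "bias_slope") - (-0.5)), 0.05)
  # least-squares property: corrected residuals on the fit set centre at 0
  self <- age_bias_correct(fit_df, fit_df)
  expect_lt(abs(mean(self$corrected_age - self$age)), 1e-9)
  # zero-bias predictions are (nearly) untouched
  clean <- tibble::tibble(age = runif(n, 5, 25))
  clean$predicted_age <- clean$age + rnorm(n, sd = 0.3)
  out0 <- age_bias_correct(clean, clean)
  expect_lt(abs(attr(out0, "bias_slope")), 0.05)
  expect_error(age_bias_correct(app, tibble::tibble(age = rep(10, 5),
                                                    predicted_age = 1:5)),
               "degenerate")
})
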