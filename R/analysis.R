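#' Brain age gap
#'
#' Predicted brain age minus chronological age: positive values indicate an
#' older-appearing brain.
#'
#' @param predicted predicted brain age (years).
#' @param chronological chronological age (years).
#' @return gap in years.
#' @export
compute_gap <- function(predicted, chronological) {
  predicted - chronological
}

#' Mean absolute error and IQR of absolute errors
#'
#' @param data tibble with `predicted_age` and `age` columns (one row per
#'   subject), or a numeric vector of gaps via `gap`.
#' @param gap optional numeric vector of gaps, used instead of `data`.
#' @return one-row tibble: `mae`, `iqr_lo`, `iqr_hi` (25th/75th percentiles of
#'   the absolute error, linear-interpolation convention), `n`.
#' @export
mae_iqr <- function(data = NULL, gap = NULL) {
  if (is.null(gap)) {
    stopifnot(is.data.frame(data), all(c("predicted_age", "age") %in% names(data)))
    gap <- compute_gap(data$predicted_age, data$age)
  }
  if (length(gap) == 0) abort("no records.")
  ae <- abs(gap)
  q <- unname(quantile(ae, c(0.25, 0.75), type = 7))
  tibble::tibble(mae = mean(ae), iqr_lo = q[1], iqr_hi = q[2], n = length(ae))
}

#' Label brain-age outliers within (age, sex) strata
#'
#' Within each stratum (integer-year chronological age bin x sex), a subject
#' is `Older` when the predicted age exceeds the stratum mean prediction by
#' more than `sd_mult` sample standard deviations, `Younger` when it falls
#' below by more than that, and `Average` otherwise. Strata with fewer than
#' `min_stratum` records are labelled `Average` with a warning.
#'
#' @param data tibble with `age`, `sex`, `predicted_age`.
#' @param sd_mult threshold multiplier (default 1).
#' @param min_stratum minimum records for a stratum SD (default 3).
#' @return `data` plus a `group` column (`Younger` / `Average` / `Older`).
#' @export
classify_gap_outliers <- function(data, sd_mult = 1, min_stratum = 3L) {
  stopifnot(all(c("age", "sex", "predicted_age") %in% names(data)))
  if (any(!complete.cases(data[, c("age", "sex", "predicted_age")]))) {
    abort("missing age/sex/predicted_age; complete the records first.")
  }
  small <- FALSE
  out <- data |>
    dplyr::mutate(.age_bin = floor(.data$age)) |>
    dplyr::group_by(.data$.age_bin, .data$sex) |>
    dplyr::mutate(group = {
      if (dplyr::n() < min_stratum) {
        small <<- TRUE
        rep("Average", dplyr::n())
      } else {
        m <- mean(.data$predicted_age)
        s <- sd(.data$predicted_age)
        dplyr::case_when(
          .data$predicted_age > m + sd_mult * s ~ "Older",
          .data$predicted_age < m - sd_mult * s ~ "Younger",
          TRUE ~ "Average")
      }
    }) |>
    dplyr::ungroup() |>
    dplyr::select(-".age_bin")
  if (small) warn("strata with fewer than `min_stratum` records labelled Average.")
  out
}

cohen_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2))
  if (sp == 0) return(0)
  (mean(x) - mean(y)) / sp
}

#' Compare volumetric measures between brain-age groups
#'
#' For every volumetric measure, sex, and outlier group (`Older` and
#' `Younger`, each against `Average`), a two-sided Mann-Whitney U test and a
#' pooled-SD Cohen's d are computed. The significance threshold is Bonferroni
#' adjusted as `alpha / (measures x sexes x pairs)` (0.05/16 = 0.003125 for
#' the default design).
#'
#' @param data tibble with `sex`, `group`, and the measure columns (join your
#'   volumetrics onto the labelled records first if they live elsewhere).
#' @param measures measure column names (default WMV, GMV, sGMV, VV).
#' @param alpha family-wise level before correction (default 0.05).
#' @param reference reference group name (default `"Average"`).
#' @return tibble with one row per (measure, sex, group): group sizes, `U`,
#'   `p_value`, `cohens_d` (group minus reference), `alpha_adjusted`,
#'   `significant`. Comparisons with an empty group are skipped and reported
#'   with `NA` statistics.
#' @export
group_compare <- function(data, measures = c("WMV", "GMV", "sGMV", "VV"),
                          alpha = 0.05, reference = "Average") {
  stopifnot(all(c("sex", "group") %in% names(data)),
            all(measures %in% names(data)))
  sexes <- sort(unique(data$sex))
  groups <- setdiff(sort(unique(data$group)), reference)
  n_comp <- length(measures) * length(sexes) * length(groups)
  alpha_adj <- alpha / n_comp
  grid <- tidyr::expand_grid(measure = measures, sex = sexes, group = groups)
  res <- purrr::pmap(grid, function(measure, sex, group) {
    x <- data[data$sex == sex & data$group == group, ][[measure]]
    y <- data[data$sex == sex & data$group == reference, ][[measure]]
    if (length(x) == 0 || length(y) == 0) {
      return(tibble::tibble(n_group = length(x), n_reference = length(y),
                            U = NA_real_, p_value = NA_real_,
                            cohens_d = NA_real_, skipped = TRUE))
    }
    wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
    tibble::tibble(n_group = length(x), n_reference = length(y),
                   U = unname(wt$statistic), p_value = wt$p.value,
                   cohens_d = cohen_d(x, y), skipped = FALSE)
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(res))
  out$alpha_adjusted <- alpha_adj
  out$significant <- !is.na(out$p_value) & out$p_value < alpha_adj
  out
}

subject_rates <- function(d, measures) {
  d <- d[order(d$age), ]
  dage <- diff(d$age)
  ok <- dage > 0
  if (!all(ok)) warn("interval with zero age difference skipped.")
  if (!any(ok)) return(NULL)
  rates <- vapply(c("predicted_age", measures), function(m) {
    mean(diff(d[[m]])[ok] / dage[ok])
  }, numeric(1))
  names(rates)[1] <- "brainage_rate"
  names(rates)[-1] <- paste0("rate_", measures)
  tibble::as_tibble(as.list(rates))
}

#' Categorise longitudinal brain-age change and test volumetric associations
#'
#' Per subject, the rate of change per year of predicted brain age and of
#' each volumetric measure is computed over consecutive visits (mean of
#' per-interval `delta value / delta age`; zero-length intervals are skipped
#' with a warning). Subjects are categorised on the brain-age rate:
#' `Accelerated` above cohort mean + `sd_mult` SD, `Decelerated` below
#' cohort mean - `sd_mult` SD, `Stable` otherwise. Each measure's rate is
#' then compared `Stable` vs `Accelerated` and `Stable` vs `Decelerated` by
#' two-sided Mann-Whitney U tests with Bonferroni adjustment
#' `alpha / (measures x 2)` (0.05/8 = 0.00625, i.e. P < 0.006, for the four
#' standard measures).
#'
#' @param data long tibble: `subject_id`, `age`, `predicted_age`, and the
#'   measure columns; >= 2 visits per subject.
#' @param measures volumetric measure columns.
#' @param sd_mult threshold multiplier on the cohort rate SD (default 1).
#' @param alpha family-wise level before correction.
#' @return list with `subjects` (per-subject rates + `category`),
#'   `comparisons` (per measure x pair test table), and `thresholds`.
#' @export
categorize_longitudinal <- function(data, measures = c("WMV", "GMV", "sGMV", "VV"),
                                    sd_mult = 1, alpha = 0.05) {
  stopifnot(all(c("subject_id", "age", "predicted_age") %in% names(data)),
            all(measures %in% names(data)))
  counts <- table(data$subject_id)
  if (any(counts < 2)) abort("every subject needs >= 2 visits.")
  subjects <- data |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(function(d, key) subject_rates(d, measures)) |>
    dplyr::ungroup()
  m <- mean(subjects$brainage_rate)
  s <- sd(subjects$brainage_rate)
  subjects$category <- dplyr::case_when(
    subjects$brainage_rate > m + sd_mult * s ~ "Accelerated",
    subjects$brainage_rate < m - sd_mult * s ~ "Decelerated",
    TRUE ~ "Stable")
  pairs <- c("Accelerated", "Decelerated")
  alpha_adj <- alpha / (length(measures) * length(pairs))
  grid <- tidyr::expand_grid(measure = measures, group = pairs)
  res <- purrr::pmap(grid, function(measure, group) {
    x <- subjects[subjects$category == group, ][[paste0("rate_", measure)]]
    y <- subjects[subjects$category == "Stable", ][[paste0("rate_", measure)]]
    if (length(x) == 0 || length(y) == 0) {
      return(tibble::tibble(n_group = length(x), n_stable = length(y),
                            U = NA_real_, p_value = NA_real_))
    }
    wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
    tibble::tibble(n_group = length(x), n_stable = length(y),
                   U = unname(wt$statistic), p_value = wt$p.value)
  })
  comparisons <- dplyr::bind_cols(grid, dplyr::bind_rows(res))
  comparisons$alpha_adjusted <- alpha_adj
  comparisons$significant <- !is.na(comparisons$p_value) &
    comparisons$p_value < alpha_adj
  list(subjects = subjects,
       comparisons = comparisons,
       thresholds = c(mean = m, sd = s,
                      upper = m + sd_mult * s, lower = m - sd_mult * s))
}

#' Compare how volumetrics explain chronological versus predicted brain age
#'
#' Fits two ordinary least squares models with the volumetric measures and
#' sex as independent variables, once with chronological age and once with
#' predicted brain age as the dependent variable, and reports each model's
#' coefficient of determination.
#'
#' @param data tibble with `age`, `predicted_age`, `sex`, and the measure
#'   columns; >= 10 rows.
#' @param measures volumetric predictors.
#' @return tibble with one row per outcome: `outcome`, `r_squared`, `n`.
#' @export
compare_age_models <- function(data, measures = c("WMV", "GMV", "sGMV", "VV")) {
  stopifnot(all(c("age", "predicted_age", "sex") %in% names(data)),
            all(measures %in% names(data)))
  if (nrow(data) < 10) abort("need >= 10 rows.")
  rhs <- paste(c(measures, "sex"), collapse = " + ")
  fit_one <- function(outcome) {
    f <- stats::as.formula(paste(outcome, "~", rhs))
    fit <- lm(f, data = data)
    if (fit$rank < length(measures) + 2) {
      abort(sprintf("rank-deficient design for outcome `%s`.", outcome))
    }
    summary(fit)$r.squared
  }
  tibble::tibble(
    outcome = c("chronological_age", "brain_age"),
    r_squared = c(fit_one("age"), fit_one("predicted_age")),
    n = nrow(data))
}

#' Age-bias correction of brain-age predictions (optional transform)
#'
#' Fits `gap ~ a * age + b` by least squares on a held-out fit set and
#' subtracts the fitted bias from the predictions of `data`:
#' `corrected = predicted - (a * age + b)`. The fit set must be disjoint from
#' the application set. Off by default in the pipeline; provided for
#' sensitivity analyses.
#'
#' @param data tibble with `age` and `predicted_age` to be corrected.
#' @param fit_data tibble (same columns) on which the bias line is estimated.
#' @return `data` plus `corrected_age`; attributes `bias_slope` and
#'   `bias_intercept` carry the fitted line.
#' @export
age_bias_correct <- function(data, fit_data) {
  stopifnot(all(c("age", "predicted_age") %in% names(data)),
            all(c("age", "predicted_age") %in% names(fit_data)))
  if (sd(fit_data$age) == 0) abort("degenerate fit: constant ages.")
  fit <- lm(gap ~ age, data = tibble::tibble(
    gap = compute_gap(fit_data$predicted_age, fit_data$age),
    age = fit_data$age))
  a <- unname(coef(fit)[2]); b <- unname(coef(fit)[1])
  out <- tibble::as_tibble(data)
  out$corrected_age <- out$predicted_age - (a * out$age + b)
  attr(out, "bias_slope") <- a
  attr(out, "bias_intercept") <- b
  out
}
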