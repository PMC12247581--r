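#' Mean ensemble of per-slice predictions
#'
#' @param predictions numeric vector of per-slice age predictions (years),
#'   length >= 1.
#' @return one-row tibble: `final_age`, `ensemble_mean`, `ensemble_sd`,
#'   `n_included`, `included` (list-column logical mask), `method`.
#' @export
mean_ensemble <- function(predictions) {
  if (length(predictions) == 0) abort("no predictions to ensemble.")
  tibble::tibble(final_age = mean(predictions),
                 ensemble_mean = mean(predictions),
                 ensemble_sd = if (length(predictions) > 1) sd(predictions) else 0,
                 n_included = length(predictions),
                 included = list(rep(TRUE, length(predictions))),
                 method = "mean")
}

#' Outlier-exclusion ensemble of per-slice predictions
#'
#' Computes the mean `m` and sample standard deviation `s` of all
#' predictions, excludes every prediction deviating from `m` by strictly
#' more than `s`, and averages the remainder. Exclusion is single-pass; when
#' `s = 0` nothing is excluded. With strict inequality at least one
#' prediction always survives, so the consensus is well defined.
#'
#' @param predictions numeric vector (>= 2 for the exclusion rule; a single
#'   prediction falls back to [mean_ensemble()] with a warning).
#' @return one-row tibble as in [mean_ensemble()], `method =
#'   "outlier_excluded"`.
#' @export
outlier_excluded_ensemble <- function(predictions) {
  if (length(predictions) < 2) {
    warn("fewer than 2 predictions: falling back to the plain mean.")
    out <- mean_ensemble(predictions)
    out$method <- "outlier_excluded"
    return(out)
  }
  m <- mean(predictions)
  s <- sd(predictions)
  keep <- abs(predictions - m) <= s
  tibble::tibble(final_age = mean(predictions[keep]),
                 ensemble_mean = m, ensemble_sd = s,
                 n_included = sum(keep), included = list(keep),
                 method = "outlier_excluded")
}

#' Ensemble per-slice predictions across a cohort
#'
#' @param predictions tibble with columns `subject_id`, `percentile`,
#'   `predicted_age` (one row per subject x slice).
#' @param method `"outlier_excluded"` (default) or `"mean"`.
#' @param percentiles optional subset of slice percentiles to use (e.g.
#'   `c(37.5, 50, 62.5)` for a 3-slice ensemble).
#' @return tibble with one row per subject: `subject_id`, `final_age`,
#'   `ensemble_mean`, `ensemble_sd`, `n_slices`, `n_included`, `method`.
#'   Subjects missing some requested slices are kept and flagged via
#'   `complete`.
#' @export
ensemble_cohort <- function(predictions, method = c("outlier_excluded", "mean"),
                            percentiles = NULL) {
  method <- match.arg(method)
  stopifnot(all(c("subject_id", "percentile", "predicted_age") %in%
                  names(predictions)))
  if (!is.null(percentiles)) {
    predictions <- dplyr::filter(predictions, .data$percentile %in% percentiles)
    expected <- length(percentiles)
  } else {
    expected <- length(unique(predictions$percentile))
  }
  fn <- if (method == "mean") mean_ensemble else outlier_excluded_ensemble
  predictions |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(function(d, key) {
      res <- if (nrow(d) == 1) {
        out <- mean_ensemble(d$predicted_age); out$method <- method; out
      } else fn(d$predicted_age)
      res$n_slices <- nrow(d)
      res$complete <- nrow(d) == expected
      res
    }) |>
    dplyr::ungroup() |>
    dplyr::select("subject_id", "final_age", "ensemble_mean", "ensemble_sd",
                  "n_slices", "n_included", "complete", "method")
}
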