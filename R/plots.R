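#' Scatter plot of predicted versus chronological age
#'
#' @param data tibble with `age` and `predicted_age`.
#' @return a ggplot object (identity line overlaid).
#' @export
plot_predictions <- function(data) {
  stopifnot(all(c("age", "predicted_age") %in% names(data)))
  ggplot2::ggplot(data, ggplot2::aes(x = .data$age, y = .data$predicted_age)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(x = "chronological age (years)",
                  y = "predicted brain age (years)") +
    ggplot2::theme_minimal()
}

#' Effect-size heatmap for group comparisons
#'
#' Tiles Cohen's d by measure and sex for each outlier group versus the
#' reference, starring comparisons significant after Bonferroni correction.
#'
#' @param comparisons output of [group_compare()].
#' @return a ggplot object.
#' @export
plot_group_effects <- function(comparisons) {
  stopifnot(all(c("measure", "sex", "group", "cohens_d") %in% names(comparisons)))
  comparisons$label <- ifelse(comparisons$significant %in% TRUE, "*", "")
  ggplot2::ggplot(comparisons,
                  ggplot2::aes(x = .data$measure, y = interaction(.data$sex, .data$group),
                               fill = .data$cohens_d)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label)) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Cohen's d") +
    ggplot2::theme_minimal()
}

#' Saliency map and selected ROIs for one slice
#'
#' @param model a fitted `diffage_model`.
#' @param slice 2D slice matrix at the model's input resolution.
#' @param k,patch_size ROI extraction parameters (defaults from the model).
#' @return a ggplot object: slice intensities with ROI boxes overlaid.
#' @export
plot_saliency <- function(model, slice, k = NULL, patch_size = NULL) {
  stopifnot(inherits(model, "diffage_model"))
  k <- k %||% model$config$k_rois
  patch_size <- patch_size %||% model$config$patch_size %||%
    max(4L, nrow(slice) %/% 4L)
  sal <- compute_saliency(slice, model$nets$tau_g)
  rois <- extract_rois(sal, slice, k = k, patch_size = patch_size)
  df <- tibble::tibble(row = as.vector(row(slice)),
                       col = as.vector(col(slice)),
                       intensity = as.vector(slice))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::geom_rect(data = rois,
                       ggplot2::aes(xmin = .data$col, xmax = .data$col + patch_size,
                                    ymin = .data$row, ymax = .data$row + patch_size),
                       inherit.aes = FALSE, colour = "red", fill = NA) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "intensity") +
    ggplot2::theme_minimal()
}
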