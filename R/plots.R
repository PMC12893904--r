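#' Plot a spatial cell map
#'
#' @param cells Spatial map tibble (`x`, `y`, `cell_type`).
#' @return A ggplot.
#' @export
plot_tissue <- function(cells) {
  check_cell_map(cells)
  ggplot2::ggplot(cells, ggplot2::aes(.data$x, .data$y,
                                      colour = .data$cell_type)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  colour = "cell type") +
    ggplot2::theme_minimal()
}

#' Plot interaction Z scores against age
#'
#' @param z_scores Tibble of [interaction_zscore()] rows across ages.
#' @return A ggplot with one panel per cell-type pair and a linear trend
#'   line.
#' @export
plot_z_trend <- function(z_scores) {
  z_scores <- as_tibble(z_scores)
  ggplot2::ggplot(z_scores, ggplot2::aes(.data$age, .data$z)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick", linewidth = 0.6) +
    ggplot2::facet_wrap(~ paste(type_a, "–", type_b)) +
    ggplot2::labs(x = "age (weeks)", y = "interaction z") +
    ggplot2::theme_minimal()
}

#' Plot spatial region calls
#'
#' @param points Data frame with `x`, `y`, `cell_id`.
#' @param regions Output of [region_call()].
#' @return A ggplot of cells coloured by region.
#' @export
plot_regions <- function(points, regions) {
  df <- dplyr::left_join(as_tibble(points), regions, by = "cell_id")
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   colour = factor(.data$region))) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = "region") +
    ggplot2::theme_minimal()
}

#' @describeIn fit_quadratic Calibration curve with its confidence band
#'   and the underlying points.
#' @param data Optional calibration data frame (`age`, `response`) to
#'   overlay.
#' @param level Band confidence level.
#' @export
autoplot.age_response_curve <- function(object, data = NULL,
                                        level = 0.95, ...) {
  grid <- seq(object$age_range[1], object$age_range[2],
              length.out = 100)
  band <- predict_band(object, grid, level = level)
  p <- ggplot2::ggplot(band, ggplot2::aes(.data$age, .data$fit)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "age (weeks)", y = "response") +
    ggplot2::theme_minimal()
  if (!is.null(data)) {
    p <- p + ggplot2::geom_point(data = as_tibble(data),
                                 ggplot2::aes(.data$age, .data$response))
  }
  p
}
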