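# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Map a predicted grid field
#'
#' @param object A `grid_field` from [predict_grid()].
#' @param grid The grid cell table (with `cell_id`, `x`, `y`) used to place
#'   the cells.
#' @param ... Unused.
#' @return A ggplot tile map of annual NO2.
#' @export
autoplot.grid_field <- function(object, grid, ...) {
  df <- dplyr::left_join(
    dplyr::mutate(object, cell_id = as.integer(.data$cell_id)),
    grid[, c("cell_id", "x", "y")], by = "cell_id")
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$no2)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = expression(NO[2] ~ (mu * g / m^3))) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste("Predicted annual NO2, scenario",
                                attr(object, "scenario") %||% ""),
                  x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}

#' Observed vs out-of-bag predicted values of a forest fit
#'
#' @param object A `forest_fit`.
#' @param ... Unused.
#' @return A ggplot scatter with the identity line and the OLS line of
#'   observed on predicted.
#' @export
autoplot.forest_fit <- function(object, ...) {
  ok <- is.finite(object$oob_predictions)
  df <- tibble::tibble(predicted = object$oob_predictions[ok],
                       observed = object$oob_predictions[ok] +
                         object$oob_errors)
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$observed)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(x = "OOB predicted NO2 (ug/m3)",
                  y = "Observed NO2 (ug/m3)",
                  title = sprintf("OOB R2 %.2f, RMSE %.2f",
                                  object$fit_stats$oob_r2,
                                  object$fit_stats$rmse)) +
    ggplot2::theme_minimal()
}

#' Attributable deaths by district and scenario
#'
#' @param districts_s1,districts_s2 Outputs of [aggregate_districts()] for
#'   the two scenarios.
#' @return A grouped bar chart of district attributable deaths.
#' @export
plot_district_hia <- function(districts_s1, districts_s2) {
  df <- dplyr::bind_rows(
    dplyr::mutate(districts_s1, scenario = "S1 (lockdown)"),
    dplyr::mutate(districts_s2, scenario = "S2 (no lockdown)"))
  ggplot2::ggplot(df, ggplot2::aes(.data$district_id,
                                   .data$attributable_deaths,
                                   fill = .data$scenario)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "district", y = "attributable deaths") +
    ggplot2::theme_minimal()
}
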