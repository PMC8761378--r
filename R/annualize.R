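# Scenario annualization: city-specific annual adjustment factors (ratio of
# campaign-window station mean to annual station mean, averaged over
# stations) convert each sampler's 1-month value into an annual estimate.
# Scenario 1 uses the observed 2020 annual mean; Scenario 2 recomputes the
# annual mean after replacing the March-May months with the counterfactual
# forest predictions.

#' Campaign-window mean per station from daily data
#'
#' Arithmetic mean of the daily values in the closed date window (default
#' February 8 to March 7, 2020, the passive-sampler monitoring period).
#' Stations with fewer than `min_days` non-missing days in the window are
#' dropped with a warning.
#'
#' @param daily Tibble with `station_id`, `date` (Date), `no2_daily`.
#' @param window Length-2 Date vector, closed interval.
#' @param min_days Minimum non-missing days required (default 20).
#' @return Tibble with `station_id` and `window_mean` (ug/m3).
#' @export
campaign_window_mean <- function(daily,
                                 window = as.Date(c("2020-02-08", "2020-03-07")),
                                 min_days = 20) {
  stopifnot(length(window) == 2)
  out <- daily |>
    dplyr::filter(.data$date >= window[1], .data$date <= window[2],
                  !is.na(.data$no2_daily)) |>
    dplyr::group_by(.data$station_id) |>
    dplyr::summarise(window_mean = mean(.data$no2_daily),
                     n_days = dplyr::n(), .groups = "drop")
  short <- out$station_id[out$n_days < min_days]
  if (length(short) > 0)
    warn(paste0("excluding station(s) with < ", min_days,
                " days in window: ", paste(short, collapse = ", ")))
  out[out$n_days >= min_days, c("station_id", "window_mean")]
}

#' Observed monthly means per station from daily data
#'
#' Calendar-month means of the daily 2020 series, the building block of the
#' observed (Scenario 1) annual mean.
#'
#' @param daily Tibble with `station_id`, `date`, `no2_daily`.
#' @return Tibble with `station_id`, `month`, `no2`.
#' @export
monthly_means_from_daily <- function(daily) {
  daily |>
    dplyr::filter(!is.na(.data$no2_daily)) |>
    dplyr::mutate(month = as.integer(format(.data$date, "%m"))) |>
    dplyr::group_by(.data$station_id, .data$month) |>
    dplyr::summarise(no2 = mean(.data$no2_daily), .groups = "drop")
}

#' Annual mean as the unweighted mean of twelve monthly values
#'
#' @param monthly Tibble with `station_id`, `month`, `no2`; all twelve
#'   months must be present per station.
#' @param day_weighted If `TRUE`, weight months by their 2020 day counts
#'   instead of equally.
#' @return Tibble with `station_id`, `annual_mean`.
#' @export
annual_mean_from_monthly <- function(monthly, day_weighted = FALSE) {
  chk <- monthly |>
    dplyr::count(.data$station_id) |>
    dplyr::filter(.data$n != 12L)
  if (nrow(chk) > 0)
    abort(paste0("station(s) without 12 monthly values: ",
                 paste(chk$station_id, collapse = ", ")),
          class = "no2_annualize_error")
  w <- if (day_weighted) days_in_month_2020 else rep(1, 12)
  monthly |>
    dplyr::group_by(.data$station_id) |>
    dplyr::summarise(
      annual_mean = sum(.data$no2 * w[.data$month]) / sum(w[.data$month]),
      .groups = "drop")
}

#' Compose the counterfactual (no-lockdown) annual mean
#'
#' Replaces the observed March, April and May monthly values with the
#' counterfactual predictions, then averages the twelve months.
#'
#' @param observed_monthly Tibble with `station_id`, `month`, `no2`
#'   (twelve months per station).
#' @param predictions Tibble with `station_id`, `month` (3, 4, 5), `point`.
#' @param day_weighted Passed to [annual_mean_from_monthly()].
#' @return Tibble with `station_id`, `annual_mean`.
#' @export
compose_counterfactual_annual <- function(observed_monthly, predictions,
                                          day_weighted = FALSE) {
  need <- predictions |>
    dplyr::count(.data$station_id) |>
    dplyr::filter(.data$n != 3L)
  if (nrow(need) > 0)
    abort(paste0("station(s) without 3 predicted months: ",
                 paste(need$station_id, collapse = ", ")),
          class = "no2_annualize_error")
  replaced <- observed_monthly |>
    dplyr::left_join(
      dplyr::select(predictions, "station_id", "month", "point"),
      by = c("station_id", "month")) |>
    dplyr::mutate(no2 = dplyr::coalesce(.data$point, .data$no2)) |>
    dplyr::select("station_id", "month", "no2")
  annual_mean_from_monthly(replaced, day_weighted)
}

#' City-level annual adjustment factors for one scenario
#'
#' Per station, the ratio of the campaign-window mean to the annual mean;
#' the city factor is the mean of the ratios, with the minimum and maximum
#' ratios kept for uncertainty propagation.
#'
#' @param window_means Tibble with `station_id`, `window_mean`.
#' @param annual_means Tibble with `station_id`, `annual_mean`.
#' @param scenario `"S1"` or `"S2"` label.
#' @param city City label.
#' @return A `scenario_factors` list: `per_station` tibble (station, ratio)
#'   and `factor_mean`, `factor_sd`, `factor_min`, `factor_max`.
#' @export
adjustment_factors <- function(window_means, annual_means,
                               scenario = "S1", city = "city") {
  joined <- dplyr::inner_join(window_means, annual_means, by = "station_id")
  if (nrow(joined) < 2)
    abort("need >= 2 stations with both window and annual means.",
          class = "no2_annualize_error")
  if (any(joined$annual_mean <= 0))
    abort("annual means must be positive.", class = "no2_annualize_error")
  ratios <- joined$window_mean / joined$annual_mean
  structure(list(
    city = city, scenario = scenario,
    per_station = tibble::tibble(station_id = joined$station_id,
                                 ratio = ratios),
    factor_mean = mean(ratios), factor_sd = sd(ratios),
    factor_min = min(ratios), factor_max = max(ratios)
  ), class = "scenario_factors")
}

#' @export
print.scenario_factors <- function(x, ...) {
  cat(sprintf("<scenario_factors> %s %s: mean %.3f (sd %.3f), min %.3f, max %.3f over %d stations\n",
              x$city, x$scenario, x$factor_mean, x$factor_sd,
              x$factor_min, x$factor_max, nrow(x$per_station)))
  invisible(x)
}

#' Annualize corrected 1-month sampler values
#'
#' Each corrected 1-month value is divided by the city factor; dividing by
#' the maximum and minimum station ratios gives the low and high annual
#' variants used for uncertainty propagation.
#'
#' @param samplers Tibble with `sampler_id` and `no2_corrected`.
#' @param factors A `scenario_factors` object.
#' @return Tibble with `sampler_id`, `scenario`, `annual_no2`,
#'   `annual_no2_lo`, `annual_no2_hi`.
#' @export
annualize <- function(samplers, factors) {
  stopifnot(inherits(factors, "scenario_factors"))
  if (factors$factor_mean <= 0)
    abort("factor_mean must be positive.", class = "no2_annualize_error")
  tibble::tibble(
    sampler_id = samplers$sampler_id,
    scenario = factors$scenario,
    annual_no2 = samplers$no2_corrected / factors$factor_mean,
    annual_no2_lo = samplers$no2_corrected / factors$factor_max,
    annual_no2_hi = samplers$no2_corrected / factors$factor_min
  )
}
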