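# Health impact assessment: census blocks are linked to the predicted NO2
# grid, all-cause deaths (redistributed to blocks by population where needed)
# are combined with an attributable fraction
#   AF = (exp(log(RR)/10 * c) - 1) / exp(log(RR)/10 * c) = 1 - RR^(-c/10)
# where c is the exposure excess over the counterfactual threshold
# (10 ug/m3, the WHO 2021 annual guideline), RR the relative risk per
# 10 ug/m3 (1.04, 95% CI 1.02-1.07, all-cause mortality).

#' Dose-response parameters for the HIA
#'
#' @param rr Relative risk per 10 ug/m3 NO2 (default 1.04).
#' @param rr_lo,rr_hi 95 percent CI bounds of the relative risk.
#' @param threshold Counterfactual concentration (ug/m3) below which no
#'   excess risk is attributed (default 10).
#' @return A `hia_params` list.
#' @export
hia_params <- function(rr = 1.04, rr_lo = 1.02, rr_hi = 1.07, threshold = 10) {
  if (rr <= 0) abort("`rr` must be positive.", class = "no2_hia_error")
  if (threshold < 0) abort("`threshold` must be >= 0.", class = "no2_hia_error")
  structure(list(rr = rr, rr_lo = rr_lo, rr_hi = rr_hi,
                 threshold = threshold), class = "hia_params")
}

#' Attributable fraction of mortality at a given exposure
#'
#' `AF = 1 - RR^(-c/10)` with `c = max(0, exposure - threshold)`: zero at or
#' below the threshold, strictly increasing above it, bounded in [0, 1).
#'
#' @param exposure Annual NO2 exposure(s), ug/m3.
#' @param params A [hia_params()] object.
#' @param rr Optionally override the relative risk (e.g. a CI bound).
#' @return Attributable fraction(s) in [0, 1).
#' @export
attributable_fraction <- function(exposure, params = hia_params(), rr = NULL) {
  rr <- rr %||% params$rr
  if (any(rr <= 0)) abort("`rr` must be positive.", class = "no2_hia_error")
  c_excess <- pmax(0, exposure - params$threshold)
  z <- exp(log(rr) / 10 * c_excess)
  (z - 1) / z
}

#' Redistribute area-level deaths to census blocks by population
#'
#' When mortality is only available at a coarser areal unit (borough), each
#' block receives deaths proportional to its share of the borough
#' population. Fractional deaths are allowed; totals are conserved exactly.
#'
#' @param area_deaths Tibble with `borough_id`, `deaths`.
#' @param block_populations Tibble with `block_id`, `borough_id`,
#'   `population`.
#' @return `block_populations` with a `deaths` column.
#' @export
redistribute_deaths <- function(area_deaths, block_populations) {
  joined <- dplyr::left_join(block_populations, area_deaths, by = "borough_id")
  bad <- joined |>
    dplyr::group_by(.data$borough_id) |>
    dplyr::summarise(pop = sum(.data$population),
                     d = dplyr::first(.data$deaths), .groups = "drop") |>
    dplyr::filter(.data$pop <= 0, .data$d > 0)
  if (nrow(bad) > 0)
    abort(paste0("borough(s) with zero population but nonzero deaths: ",
                 paste(bad$borough_id, collapse = ", ")),
          class = "no2_hia_error")
  joined |>
    dplyr::group_by(.data$borough_id) |>
    dplyr::mutate(deaths = .data$deaths * .data$population /
                    sum(.data$population)) |>
    dplyr::ungroup()
}

#' Link census blocks to the predicted grid field
#'
#' Each block's exposure is the unweighted mean NO2 of all grid cells whose
#' rectangle intersects the block rectangle (non-strict: shared edges and
#' corners count). An area-weighted mean is available behind a flag.
#'
#' @param blocks Tibble with `block_id`, `xmin`, `xmax`, `ymin`, `ymax`.
#' @param field A `grid_field` tibble (`cell_id`, `no2`, ...).
#' @param grid Grid cell table with `cell_id`, `xmin`, `xmax`, `ymin`,
#'   `ymax`.
#' @param column Field column to aggregate (default `"no2"`).
#' @param area_weighted If `TRUE`, weight intersecting cells by overlap area.
#' @return `blocks` with an added `exposure` column (ug/m3).
#' @export
link_blocks_to_grid <- function(blocks, field, grid, column = "no2",
                                area_weighted = FALSE) {
  vals <- field[[column]][match(grid$cell_id, field$cell_id)]
  exposure <- numeric(nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    hit <- rects_intersect(grid$xmin, grid$xmax, grid$ymin, grid$ymax,
                           blocks$xmin[i], blocks$xmax[i],
                           blocks$ymin[i], blocks$ymax[i])
    if (!any(hit))
      abort(paste0("block intersects no grid cell: ", blocks$block_id[i]),
            class = "no2_hia_error")
    if (area_weighted) {
      w <- pmax(0, pmin(grid$xmax[hit], blocks$xmax[i]) -
                  pmax(grid$xmin[hit], blocks$xmin[i])) *
        pmax(0, pmin(grid$ymax[hit], blocks$ymax[i]) -
               pmax(grid$ymin[hit], blocks$ymin[i]))
      if (sum(w) == 0) w <- rep(1, sum(hit))
      exposure[i] <- sum(vals[hit] * w) / sum(w)
    } else {
      exposure[i] <- mean(vals[hit])
    }
  }
  blocks$exposure <- exposure
  blocks
}

#' Block-level and city-level health impact for one scenario
#'
#' Computes per-block attributable fractions and deaths
#' (`AF * deaths`), and city totals: total attributable deaths, their share
#' of total mortality, population-weighted exposure, and the percent of the
#' population above 40 ug/m3 (the EU annual limit).
#'
#' @param blocks Tibble with `block_id`, `population`, `deaths`, `exposure`
#'   (and optionally `district_id`).
#' @param params A [hia_params()].
#' @param scenario Scenario label.
#' @param rr Optional relative-risk override (CI bound).
#' @return List with `blocks` (per-block `af`, `attributable_deaths`) and
#'   `city` (a one-row `city_hia` tibble).
#' @export
block_hia <- function(blocks, params = hia_params(), scenario = "S1",
                      rr = NULL) {
  af <- attributable_fraction(blocks$exposure, params, rr = rr)
  out <- blocks
  out$scenario <- scenario
  out$af <- af
  out$attributable_deaths <- af * blocks$deaths
  city <- tibble::tibble(
    scenario = scenario,
    total_attributable = sum(out$attributable_deaths),
    total_deaths = sum(blocks$deaths),
    share_of_total_mortality = sum(out$attributable_deaths) /
      sum(blocks$deaths),
    pop_weighted_exposure = sum(blocks$population * blocks$exposure) /
      sum(blocks$population),
    pct_pop_above_40 = 100 * sum(blocks$population[blocks$exposure > 40]) /
      sum(blocks$population)
  )
  class(city) <- c("city_hia", class(city))
  list(blocks = out, city = city)
}

#' Lockdown effect: difference between the two scenario HIAs
#'
#' @param city_s1,city_s2 One-row `city_hia` tibbles for the lockdown (S1)
#'   and no-lockdown (S2) scenarios.
#' @return One-row tibble: `prevented_deaths` (S2 minus S1 attributable
#'   totals), `pct_change` (relative to S1), `exposure_change_pct`
#'   (population-weighted exposure shift S1 to S2).
#' @export
scenario_delta <- function(city_s1, city_s2) {
  prevented <- city_s2$total_attributable - city_s1$total_attributable
  tibble::tibble(
    prevented_deaths = prevented,
    pct_change = relative_change(city_s1$total_attributable,
                                 city_s2$total_attributable),
    exposure_change_pct = relative_change(city_s1$pop_weighted_exposure,
                                          city_s2$pop_weighted_exposure)
  )
}

#' Aggregate block-level HIA to districts
#'
#' @param block_hia_tbl The `blocks` element of [block_hia()] with a
#'   `district_id` column.
#' @return Tibble per district: population, deaths, attributable deaths,
#'   attributable mortality rate per 100,000, mean exposure.
#' @export
aggregate_districts <- function(block_hia_tbl) {
  if (any(is.na(block_hia_tbl$district_id)))
    abort("every block must be mapped to a district.",
          class = "no2_hia_error")
  block_hia_tbl |>
    dplyr::group_by(.data$district_id) |>
    dplyr::summarise(
      population = sum(.data$population),
      deaths = sum(.data$deaths),
      attributable_deaths = sum(.data$attributable_deaths),
      attributable_rate_1e5 = 1e5 * sum(.data$attributable_deaths) /
        sum(.data$population),
      mean_exposure = sum(.data$population * .data$exposure) /
        sum(.data$population),
      .groups = "drop")
}

#' Uncertainty ledger: attributable-death ranges by source
#'
#' Re-evaluates the city totals under alternative complete inputs: for each
#' named variant, a pair of block tables (with `exposure` set from e.g. the
#' min/max adjustment factors or the OOB field bounds) gives a (lo, hi)
#' total; the relative-risk CI is propagated separately at the point
#' exposures.
#'
#' @param point_blocks Block table of the point run (exposure set).
#' @param variants Named list; each element is a list with `lo` and `hi`
#'   block tables (same schema as `point_blocks`). Elements that are `NULL`
#'   are skipped with a warning.
#' @param params A [hia_params()].
#' @param scenario Scenario label.
#' @return Tibble with `source`, `lo`, `hi` (attributable-death totals);
#'   the first row, `point`, repeats the point estimate, and the `rr_ci`
#'   row gives the epidemiological CI.
#' @export
uncertainty_ledger <- function(point_blocks, variants = list(),
                               params = hia_params(), scenario = "S1") {
  total <- function(blocks, rr = NULL)
    block_hia(blocks, params, scenario, rr = rr)$city$total_attributable
  point <- total(point_blocks)
  rows <- list(tibble::tibble(source = "point", lo = point, hi = point))
  rows <- c(rows, list(tibble::tibble(
    source = "rr_ci",
    lo = total(point_blocks, rr = params$rr_lo),
    hi = total(point_blocks, rr = params$rr_hi))))
  for (nm in names(variants)) {
    v <- variants[[nm]]
    if (is.null(v) || is.null(v$lo) || is.null(v$hi)) {
      warn(paste0("variant inputs missing for '", nm, "'; skipped."))
      next
    }
    pair <- sort(c(total(v$lo), total(v$hi)))
    rows <- c(rows, list(tibble::tibble(source = nm,
                                        lo = pair[1], hi = pair[2])))
  }
  dplyr::bind_rows(rows)
}
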