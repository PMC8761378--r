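# Synthetic-city generator: a self-consistent urban domain (grid, roads,
# land-cover, stations, passive samplers, census blocks, 2016-2020 NO2 series
# with a known injected lockdown multiplier) so that every downstream stage of
# the pipeline can be validated against recorded ground truth.

#' Configuration for the synthetic city generator
#'
#' All concentrations are in ug/m3, all lengths in metres. The defaults are
#' chosen to emulate a mid-sized, traffic-dominated European city: a
#' winter-high seasonal NO2 cycle, a multiplicative lockdown dip in
#' March-May 2020, a traffic-driven spatial field, and a passive-sampler
#' campaign that under-reads the reference stations by a known accuracy
#' factor.
#'
#' @param city_name Label carried through outputs.
#' @param cell_size Grid cell edge length in metres.
#' @param n_cells_x,n_cells_y Grid dimensions (cells).
#' @param n_stations Number of air-quality-network stations (>= 2).
#' @param n_samplers Number of passive samplers deployed.
#' @param n_blocks Target number of census blocks (tiled rectangles).
#' @param n_districts Number of sub-metropolitan districts.
#' @param seasonal_amplitude Relative amplitude of the winter-high seasonal
#'   NO2 cycle: month m has multiplier `1 + A * cos(2*pi*(m-1)/12)`.
#' @param lockdown_multiplier Multiplicative lockdown effect `lambda` in
#'   (0, 1] applied to March-May 2020 concentrations.
#' @param background_no2 Regional background concentration (ug/m3).
#' @param traffic_coefficient Slope of NO2 on log(1 + traffic load)
#'   (ug/m3 per log-unit of m * vehicles/day).
#' @param kernel_radius Radius (m) of the disc kernel smoothing the traffic
#'   field; emulates dispersion away from the emitting road.
#' @param sampler_noise_sd Log-scale sd of multiplicative sampler
#'   measurement noise.
#' @param station_noise_sd Log-scale sd of station monthly residual noise.
#' @param daily_noise_sd Log-scale sd of daily-within-month noise.
#' @param accuracy_factor True passive/reference ratio the samplers are
#'   generated with (they under-read when < 1); recovered by QC calibration.
#' @param population_total City population (persons).
#' @param death_rate All-cause deaths per person-year.
#' @param frac_indoor,frac_low_height,frac_outside Fractions of samplers that
#'   are ineligible (indoor, mounted below 3 m, outside the boundary).
#' @param seed Integer seed; the whole city is deterministic given it.
#' @return A `city_config` list.
#' @export
city_config <- function(city_name = "Synthia",
                        cell_size = 100,
                        n_cells_x = 30,
                        n_cells_y = 30,
                        n_stations = 20,
                        n_samplers = 300,
                        n_blocks = 64,
                        n_districts = 8,
                        seasonal_amplitude = 0.45,
                        lockdown_multiplier = 0.6,
                        background_no2 = 12,
                        traffic_coefficient = 1.8,
                        kernel_radius = 250,
                        sampler_noise_sd = 0.08,
                        station_noise_sd = 0.05,
                        daily_noise_sd = 0.05,
                        accuracy_factor = 0.92,
                        population_total = 5e4,
                        death_rate = 0.011,
                        frac_indoor = 0.02,
                        frac_low_height = 0.02,
                        frac_outside = 0.02,
                        seed = 1L) {
  cfg <- list(
    city_name = city_name, cell_size = cell_size,
    n_cells_x = as.integer(n_cells_x), n_cells_y = as.integer(n_cells_y),
    n_stations = as.integer(n_stations), n_samplers = as.integer(n_samplers),
    n_blocks = as.integer(n_blocks), n_districts = as.integer(n_districts),
    seasonal_amplitude = seasonal_amplitude,
    lockdown_multiplier = lockdown_multiplier,
    background_no2 = background_no2,
    traffic_coefficient = traffic_coefficient,
    kernel_radius = kernel_radius,
    sampler_noise_sd = sampler_noise_sd,
    station_noise_sd = station_noise_sd,
    daily_noise_sd = daily_noise_sd,
    accuracy_factor = accuracy_factor,
    population_total = population_total,
    death_rate = death_rate,
    frac_indoor = frac_indoor, frac_low_height = frac_low_height,
    frac_outside = frac_outside,
    seed = as.integer(seed)
  )
  validate_city_config(cfg)
  structure(cfg, class = "city_config")
}

validate_city_config <- function(cfg) {
  if (!is.numeric(cfg$cell_size) || cfg$cell_size <= 0)
    abort("`cell_size` must be positive.", class = "no2_config_error")
  if (cfg$n_cells_x < 2 || cfg$n_cells_y < 2)
    abort("grid must be at least 2 x 2 cells.", class = "no2_config_error")
  lam <- cfg$lockdown_multiplier
  if (!is.numeric(lam) || lam <= 0 || lam > 1)
    abort("`lockdown_multiplier` must lie in (0, 1].", class = "no2_config_error")
  if (cfg$n_stations < 2)
    abort("`n_stations` must be >= 2 (ratios need >= 1, min/max need >= 2).",
          class = "no2_config_error")
  for (f in c("n_samplers", "n_blocks", "n_districts", "population_total"))
    if (cfg[[f]] <= 0) abort(paste0("`", f, "` must be positive."),
                             class = "no2_config_error")
  if (cfg$death_rate < 0 || cfg$accuracy_factor <= 0)
    abort("`death_rate` must be >= 0 and `accuracy_factor` > 0.",
          class = "no2_config_error")
  invisible(cfg)
}

# run code under a seed without clobbering the caller's RNG stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Winter-high seasonal NO2 multiplier
#'
#' `1 + A * cos(2*pi*(month-1)/12)`: peaks in January, troughs in July, and
#' averages exactly 1 over the twelve months.
#'
#' @param month Integer month(s) in 1..12.
#' @param amplitude Relative amplitude `A` (dimensionless).
#' @return Numeric multiplier(s).
#' @export
seasonal_cycle <- function(month, amplitude) {
  1 + amplitude * cos(2 * pi * (month - 1) / 12)
}

#' Analytic campaign-window/annual concentration ratio of the generator
#'
#' The passive-sampler campaign runs February 8 to March 7, 2020 (29 days:
#' 22 in February, 7 in March). Relative to the 2020 annual mean of twelve
#' monthly values, the expected window/annual ratio is a closed form of the
#' seasonal cycle and the lockdown multiplier (which scales the March days in
#' the window and the March-May terms of the annual mean).
#'
#' @param seasonal_amplitude Seasonal amplitude `A`.
#' @param lockdown_multiplier Lockdown multiplier `lambda`.
#' @return The expected campaign-window mean divided by the annual mean.
#' @export
campaign_window_factor <- function(seasonal_amplitude, lockdown_multiplier = 1) {
  s <- seasonal_cycle(1:12, seasonal_amplitude)
  lam <- lockdown_multiplier
  window <- (22 * s[2] + 7 * lam * s[3]) / 29
  annual <- (sum(s[-(3:5)]) + lam * sum(s[3:5])) / 12
  window / annual
}

#' Seasonal amplitude that yields a given campaign-window/annual ratio
#'
#' Inverse of [campaign_window_factor()] at `lambda = 1`, where the ratio is
#' linear in the amplitude.
#'
#' @param ratio Target window/annual ratio (e.g. 1.5).
#' @return The seasonal amplitude `A`.
#' @export
amplitude_for_window_ratio <- function(ratio) {
  s1 <- campaign_window_factor(1) - campaign_window_factor(0)
  (ratio - 1) / s1
}

days_in_month_2020 <- c(31L, 29L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)

#' Generate a synthetic city
#'
#' Builds the full study domain: a rectangular grid, road network with
#' vehicle densities, land-cover and population rasters, air-quality stations
#' with monthly 2016-2020 NO2 + meteorology series and daily 2020 series, a
#' passive-sampler campaign (February 8 - March 7, 2020), census blocks with
#' Poisson death counts, and a truth record holding the annual NO2 fields
#' with and without the injected lockdown effect.
#'
#' @param config A [city_config()].
#' @return A `synthetic_city` list of tibbles; see Details.
#' @details
#' Components: `grid` (cells with centroids and the per-cell annual field),
#' `roads`, `landcover`, `traffic_lights`, `rasters` (population, elevation,
#' imperviousness, night lights per cell), `poi` (airport/port), `boundary`
#' (closed rectangle polygon), `stations`, `stations_monthly`,
#' `stations_daily_2020`, `samplers`, `blocks`, `cell_blocks` and `truth`.
#' The truth record stores the cell-level annual fields for the lockdown
#' (`true_s1`) and no-lockdown (`true_s2`) scenarios, the injected
#' `lambda`, the campaign-window field, and block-level attributable-death
#' totals computed from the true exposures with default dose-response
#' parameters.
#' @export
generate_city <- function(config) {
  validate_city_config(config)
  with_seed(config$seed, generate_city_impl(config))
}

generate_city_impl <- function(cfg) {
  cs <- cfg$cell_size
  nx <- cfg$n_cells_x
  ny <- cfg$n_cells_y
  ext_x <- nx * cs
  ext_y <- ny * cs

  # grid, row-major from the south-west corner
  grid <- tidyr::expand_grid(iy = seq_len(ny), ix = seq_len(nx)) |>
    dplyr::mutate(
      cell_id = (.data$iy - 1L) * nx + .data$ix,
      x = (.data$ix - 0.5) * cs,
      y = (.data$iy - 0.5) * cs,
      xmin = (.data$ix - 1) * cs, xmax = .data$ix * cs,
      ymin = (.data$iy - 1) * cs, ymax = .data$iy * cs
    ) |>
    dplyr::relocate("cell_id")

  boundary <- tibble::tibble(
    x = c(0, ext_x, ext_x, 0), y = c(0, 0, ext_y, ext_y)
  )

  roads <- make_roads(ext_x, ext_y)
  traffic_lights <- make_traffic_lights(roads)

  # rasterized traffic load (m * veh/day per cell), then disc-kernel smoothing
  load <- rasterize_traffic(roads, grid, cs)
  load_s <- smooth_disc(load, grid$x, grid$y, cfg$kernel_radius)
  field_s2 <- cfg$background_no2 + cfg$traffic_coefficient * log1p(load_s)

  grid$traffic_load <- load
  grid$no2_annual_s2 <- field_s2

  # population concentrated towards the centre, lognormal heterogeneity
  dcent <- sqrt((grid$x - ext_x / 2)^2 + (grid$y - ext_y / 2)^2)
  w <- exp(-dcent / (0.35 * max(ext_x, ext_y))) * exp(rnorm(nrow(grid), 0, 0.3))
  population <- cfg$population_total * w / sum(w)

  urban_q <- quantile(population, 0.55, type = 7)
  landclass <- ifelse(population > urban_q, "urban_fabric", "natural")
  # a couple of green patches and an industrial strip by the highway
  green <- patch_cells(grid, ext_x, ext_y, n = 2, frac = 0.12)
  landclass[green] <- "green_urban"
  hw <- roads[roads$type == "highway", ][1, ]
  ind <- abs(grid$y - (hw$y1 + hw$y2) / 2) < 2 * cs & grid$x > 0.7 * ext_x
  landclass[ind] <- "industrial"

  rasters <- tibble::tibble(
    cell_id = grid$cell_id,
    population = population,
    elevation = 120 + 0.01 * grid$x + 0.004 * grid$y + rnorm(nrow(grid), 0, 2),
    imperviousness = pmin(100, pmax(0, 100 * population / max(population) +
                                      rnorm(nrow(grid), 0, 5))),
    night_lights = pmax(0, 5 + 40 * population / max(population) +
                          rnorm(nrow(grid), 0, 1)),
    landcover = landclass
  )
  landcover <- rasters[, c("cell_id", "landcover")]

  poi <- tibble::tibble(
    kind = c("airport", "port"),
    x = c(ext_x * 1.3, -0.25 * ext_x),
    y = c(-0.3 * ext_y, ext_y * 0.5)
  )

  # stations: spread over distinct cells
  st_cells <- sample(grid$cell_id, cfg$n_stations)
  stations <- tibble::tibble(
    station_id = sprintf("ST%02d", seq_len(cfg$n_stations)),
    cell_id = st_cells,
    x = grid$x[match(st_cells, grid$cell_id)],
    y = grid$y[match(st_cells, grid$cell_id)]
  )

  met <- make_meteorology()
  stations_monthly <- make_station_monthly(cfg, stations, grid, met)
  stations_daily_2020 <- make_station_daily(cfg, stations_monthly)

  # passive-sampler campaign, Feb 8 - Mar 7 2020
  wfac <- campaign_window_factor(cfg$seasonal_amplitude, cfg$lockdown_multiplier)
  samplers <- make_samplers(cfg, grid, ext_x, ext_y, wfac)

  blocks <- make_blocks(cfg, grid, rasters)
  cell_blocks <- blocks$cell_blocks
  blocks <- blocks$blocks

  # truth record
  lam <- cfg$lockdown_multiplier
  s <- seasonal_cycle(1:12, cfg$seasonal_amplitude)
  s35 <- sum(s[3:5])
  s1_factor <- (12 - s35 * (1 - lam)) / 12  # exactly 1 when lam = 1
  true_s1 <- field_s2 * s1_factor
  truth_cells <- tibble::tibble(
    cell_id = grid$cell_id,
    true_s2 = field_s2,
    true_s1 = true_s1,
    campaign_field = field_s2 * wfac
  )
  truth <- make_truth(truth_cells, blocks, cell_blocks, grid, lam, wfac)
  truth$sampler_truth <- samplers$truth

  city <- list(
    config = cfg, grid = grid, boundary = boundary, roads = roads,
    traffic_lights = traffic_lights, landcover = landcover, rasters = rasters,
    poi = poi, stations = stations, stations_monthly = stations_monthly,
    stations_daily_2020 = stations_daily_2020, samplers = samplers$samplers,
    blocks = blocks, cell_blocks = cell_blocks, truth = truth
  )
  structure(city, class = "synthetic_city")
}

make_roads <- function(ext_x, ext_y) {
  rbind(
    tibble::tibble(type = "highway", n = 1,
                   x1 = -0.05 * ext_x, y1 = 0.8 * ext_y,
                   x2 = 1.05 * ext_x, y2 = 0.78 * ext_y),
    tibble::tibble(type = "major", n = 3,
                   x1 = c(0.5, 0, 0.15) * ext_x, y1 = c(-0.02, 0.35, 1.02) * ext_y,
                   x2 = c(0.52, 1, 0.9) * ext_x, y2 = c(1.02, 0.4, -0.02) * ext_y),
    tibble::tibble(type = "secondary", n = 6,
                   x1 = runif(6, 0, ext_x), y1 = runif(6, 0, ext_y),
                   x2 = runif(6, 0, ext_x), y2 = runif(6, 0, ext_y)),
    tibble::tibble(type = "local", n = 20,
                   x1 = runif(20, 0, ext_x), y1 = runif(20, 0, ext_y),
                   x2 = NA_real_, y2 = NA_real_)
  ) |>
    (\(d) {
      loc <- d$type == "local"
      ang <- runif(sum(loc), 0, 2 * pi)
      len <- runif(sum(loc), 0.05, 0.15) * ext_x
      d$x2[loc] <- d$x1[loc] + len * cos(ang)
      d$y2[loc] <- d$y1[loc] + len * sin(ang)
      d
    })() |>
    dplyr::mutate(
      road_id = sprintf("R%03d", dplyr::row_number()),
      density_light = c(highway = 40000, major = 15000,
                        secondary = 6000, local = 1500)[.data$type] *
        exp(rnorm(dplyr::n(), 0, 0.2)),
      density_heavy = 0.15 * .data$density_light * exp(rnorm(dplyr::n(), 0, 0.3))
    ) |>
    dplyr::select("road_id", "type", "x1", "y1", "x2", "y2",
                  "density_light", "density_heavy")
}

make_traffic_lights <- function(roads) {
  src <- roads[roads$type %in% c("major", "secondary"), ]
  k <- 5L
  t <- runif(nrow(src) * k)
  idx <- rep(seq_len(nrow(src)), each = k)
  tibble::tibble(
    light_id = sprintf("TL%03d", seq_along(t)),
    x = src$x1[idx] + t * (src$x2[idx] - src$x1[idx]),
    y = src$y1[idx] + t * (src$y2[idx] - src$y1[idx])
  )
}

# accumulate road length * density into grid cells by sampling points along
# each segment at fine spacing
rasterize_traffic <- function(roads, grid, cs) {
  nx <- max(grid$ix)
  ny <- max(grid$iy)
  load <- numeric(nrow(grid))
  step <- cs / 4
  for (i in seq_len(nrow(roads))) {
    len <- sqrt((roads$x2[i] - roads$x1[i])^2 + (roads$y2[i] - roads$y1[i])^2)
    npt <- max(2L, ceiling(len / step))
    t <- (seq_len(npt) - 0.5) / npt
    px <- roads$x1[i] + t * (roads$x2[i] - roads$x1[i])
    py <- roads$y1[i] + t * (roads$y2[i] - roads$y1[i])
    ix <- floor(px / cs) + 1L
    iy <- floor(py / cs) + 1L
    keep <- ix >= 1L & ix <= nx & iy >= 1L & iy <= ny
    if (!any(keep)) next
    id <- (iy[keep] - 1L) * nx + ix[keep]
    seg_len <- len / npt
    dens <- roads$density_light[i] + roads$density_heavy[i]
    tab <- tabulate(id, nbins = nrow(grid))
    load <- load + tab * seg_len * dens
  }
  load
}

# disc-kernel mean over cells within `radius` of each cell centroid
smooth_disc <- function(values, x, y, radius) {
  n <- length(values)
  out <- numeric(n)
  for (i in seq_len(n)) {
    within <- (x - x[i])^2 + (y - y[i])^2 <= radius^2
    out[i] <- mean(values[within])
  }
  out
}

patch_cells <- function(grid, ext_x, ext_y, n, frac) {
  hit <- rep(FALSE, nrow(grid))
  for (i in seq_len(n)) {
    cx <- runif(1, 0.1, 0.9) * ext_x
    cy <- runif(1, 0.1, 0.9) * ext_y
    r <- frac * min(ext_x, ext_y)
    hit <- hit | ((grid$x - cx)^2 + (grid$y - cy)^2 <= r^2)
  }
  hit
}

# city-wide monthly meteorology 2016-2020: seasonal climatology + AR(1)
# anomalies; the anomalies (not the climatology) drive the NO2 met effect so
# that the effect averages ~1 within each calendar month
make_meteorology <- function() {
  months <- tidyr::expand_grid(year = 2016:2020, month = 1:12)
  m <- months$month
  n <- nrow(months)
  ar1 <- function(sd, phi = 0.5) {
    e <- rnorm(n, 0, sd)
    x <- numeric(n)
    x[1] <- e[1]
    for (i in 2:n) x[i] <- phi * x[i - 1] + e[i]
    x
  }
  months |>
    dplyr::mutate(
      temp_clim = 13 - 9 * cos(2 * pi * (m - 1) / 12),
      temp_anom = ar1(1.5),
      temperature = .data$temp_clim + .data$temp_anom,
      dew_point = .data$temperature - 5 + rnorm(n, 0, 1),
      pres_clim = 1015 + 4 * cos(2 * pi * (m - 1) / 12),
      pres_anom = ar1(3),
      pressure_sea_level = .data$pres_clim + .data$pres_anom,
      rain_clim = pmax(10, 60 + 30 * sin(2 * pi * (m + 2) / 12)),
      rain_anom = ar1(15),
      rain_cum = pmax(0, .data$rain_clim + .data$rain_anom),
      wind_clim = 2.5 + 0.6 * cos(2 * pi * (m - 7) / 12),
      wind_anom = ar1(0.4),
      wind_speed = pmax(0.3, .data$wind_clim + .data$wind_anom),
      wind_dir = runif(n, 0, 360),
      met_effect = exp(-0.030 * .data$temp_anom
                       - 0.120 * (.data$wind_speed - .data$wind_clim)
                       - 0.0015 * (.data$rain_cum - .data$rain_clim)
                       + 0.0040 * .data$pres_anom)
    )
}

make_station_monthly <- function(cfg, stations, grid, met) {
  base <- grid$no2_annual_s2[match(stations$cell_id, grid$cell_id)]
  lam <- cfg$lockdown_multiplier
  out <- tidyr::expand_grid(station_id = stations$station_id,
                            year = 2016:2020, month = 1:12) |>
    dplyr::left_join(met, by = c("year", "month")) |>
    dplyr::left_join(tibble::tibble(station_id = stations$station_id,
                                    base_no2 = base),
                     by = "station_id")
  seas <- seasonal_cycle(out$month, cfg$seasonal_amplitude)
  lock <- ifelse(out$year == 2020 & out$month %in% 3:5, lam, 1)
  noise <- exp(rnorm(nrow(out), 0, cfg$station_noise_sd))
  out$no2 <- out$base_no2 * seas * out$met_effect * lock * noise
  out |>
    dplyr::select("station_id", "year", "month", "no2", "dew_point",
                  "temperature", "pressure_sea_level", "rain_cum",
                  "wind_dir", "wind_speed")
}

# daily 2020 series: monthly value x smooth within-month modulation (mean 1
# over each full month) x lognormal daily noise
make_station_daily <- function(cfg, stations_monthly) {
  m2020 <- stations_monthly[stations_monthly$year == 2020, ]
  dates <- seq(as.Date("2020-01-01"), as.Date("2020-12-31"), by = "day")
  mo <- as.integer(format(dates, "%m"))
  dom <- as.integer(format(dates, "%d"))
  ndays <- days_in_month_2020[mo]
  modulation <- 1 + 0.1 * sin(2 * pi * dom / ndays)
  out <- tidyr::expand_grid(station_id = unique(m2020$station_id),
                            date = dates)
  out$month <- as.integer(format(out$date, "%m"))
  out <- dplyr::left_join(out, m2020[, c("station_id", "month", "no2")],
                          by = c("station_id", "month"))
  out$no2_daily <- out$no2 * rep(modulation, times = length(unique(m2020$station_id))) *
    exp(rnorm(nrow(out), 0, cfg$daily_noise_sd))
  out[, c("station_id", "date", "no2_daily")]
}

make_samplers <- function(cfg, grid, ext_x, ext_y, wfac) {
  n <- cfg$n_samplers
  x <- runif(n, 0, ext_x)
  y <- runif(n, 0, ext_y)
  n_out <- round(cfg$frac_outside * n)
  if (n_out > 0) {
    idx <- sample(n, n_out)
    x[idx] <- ext_x * runif(n_out, 1.02, 1.2)  # displaced east of the border
  }
  # nearest cell (points outside clamp to edge cells)
  ix <- pmin(cfg$n_cells_x, pmax(1L, floor(x / cfg$cell_size) + 1L))
  iy <- pmin(cfg$n_cells_y, pmax(1L, floor(y / cfg$cell_size) + 1L))
  cell_id <- (iy - 1L) * cfg$n_cells_x + ix
  true_window <- grid$no2_annual_s2[match(cell_id, grid$cell_id)] * wfac
  indoor <- runif(n) < cfg$frac_indoor
  height <- runif(n, 3, 4.5)
  n_low <- round(cfg$frac_low_height * n)
  if (n_low > 0) height[sample(n, n_low)] <- runif(n_low, 1, 2.9)
  raw <- true_window * cfg$accuracy_factor * exp(rnorm(n, 0, cfg$sampler_noise_sd))
  samplers <- tibble::tibble(
    sampler_id = sprintf("PS%04d", seq_len(n)),
    x = x, y = y, height_m = height, indoor = indoor,
    no2_raw = raw, cell_id = cell_id
  )
  truth <- tibble::tibble(sampler_id = samplers$sampler_id,
                          true_window_no2 = true_window)
  list(samplers = samplers, truth = truth)
}

make_blocks <- function(cfg, grid, rasters) {
  nb <- cfg$n_blocks
  by <- max(1L, floor(sqrt(nb)))
  while (nb %% by != 0L) by <- by - 1L
  bx <- nb %/% by
  # contiguous ranges of cell columns/rows per block
  cutx <- as.integer(cut(grid$ix, breaks = bx, labels = FALSE))
  cuty <- as.integer(cut(grid$iy, breaks = by, labels = FALSE))
  bidx <- (cuty - 1L) * bx + cutx
  cell_blocks <- tibble::tibble(cell_id = grid$cell_id,
                                block_id = sprintf("B%03d", bidx))
  pop_cell <- rasters$population
  bdat <- dplyr::tibble(block_id = cell_blocks$block_id,
                        population = pop_cell,
                        xmin = grid$xmin, xmax = grid$xmax,
                        ymin = grid$ymin, ymax = grid$ymax) |>
    dplyr::group_by(.data$block_id) |>
    dplyr::summarise(population = sum(.data$population),
                     xmin = min(.data$xmin), xmax = max(.data$xmax),
                     ymin = min(.data$ymin), ymax = max(.data$ymax),
                     .groups = "drop")
  # districts: contiguous chunks of the block grid
  ids <- sort(unique(bdat$block_id))
  dist_of <- setNames(
    sprintf("D%02d", as.integer(cut(seq_along(ids), breaks = cfg$n_districts,
                                    labels = FALSE))),
    ids
  )
  bdat$district_id <- unname(dist_of[bdat$block_id])
  bdat$deaths <- rpois(nrow(bdat), bdat$population * cfg$death_rate)
  list(blocks = bdat[, c("block_id", "district_id", "xmin", "xmax",
                         "ymin", "ymax", "population", "deaths")],
       cell_blocks = cell_blocks)
}

make_truth <- function(truth_cells, blocks, cell_blocks, grid, lam, wfac) {
  params <- hia_params()
  bl_exp <- dplyr::left_join(cell_blocks, truth_cells, by = "cell_id") |>
    dplyr::group_by(.data$block_id) |>
    dplyr::summarise(exp_s1 = mean(.data$true_s1),
                     exp_s2 = mean(.data$true_s2), .groups = "drop") |>
    dplyr::left_join(blocks[, c("block_id", "deaths", "population")],
                     by = "block_id")
  af1 <- attributable_fraction(bl_exp$exp_s1, params)
  af2 <- attributable_fraction(bl_exp$exp_s2, params)
  attr1 <- sum(af1 * bl_exp$deaths)
  attr2 <- sum(af2 * bl_exp$deaths)
  list(
    cells = truth_cells,
    lambda = lam,
    campaign_factor = wfac,
    true_attributable_s1 = attr1,
    true_attributable_s2 = attr2,
    true_af_s1 = attr1 / sum(bl_exp$deaths),
    true_af_s2 = attr2 / sum(bl_exp$deaths),
    true_prevented = attr2 - attr1
  )
}

#' @export
print.synthetic_city <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<synthetic_city> %s: %d x %d cells of %g m, %d stations, %d samplers, %d blocks\n",
    cfg$city_name, cfg$n_cells_x, cfg$n_cells_y, cfg$cell_size,
    cfg$n_stations, nrow(x$samplers), nrow(x$blocks)))
  cat(sprintf("  lockdown multiplier lambda = %.2f; campaign factor = %.3f\n",
              x$truth$lambda, x$truth$campaign_factor))
  invisible(x)
}

#' Displace sampler values to create artificial outliers
#'
#' Test fixture for the strong-outlier rule: returns a copy of the sampler
#' table with `k` randomly chosen raw values displaced by `magnitude`, and a
#' logical `displaced` column recording which.
#'
#' @param samplers Sampler tibble with a `no2_raw` column.
#' @param k Number of values to displace (`k <= nrow(samplers)`).
#' @param magnitude Displacement in ug/m3 (added to the raw value).
#' @return The modified tibble with a `displaced` column.
#' @export
inject_outliers <- function(samplers, k, magnitude) {
  if (k > nrow(samplers))
    abort("`k` cannot exceed the number of samplers.", class = "no2_config_error")
  samplers$displaced <- FALSE
  if (k > 0) {
    idx <- sample(nrow(samplers), k)
    samplers$no2_raw[idx] <- samplers$no2_raw[idx] + magnitude
    samplers$displaced[idx] <- TRUE
  }
  samplers
}
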