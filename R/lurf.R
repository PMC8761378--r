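# Land Use Random Forest (LURF): multi-radius circular-buffer predictors
# around points (passive samplers or grid-cell centroids) feed a regression
# forest of annual NO2, which is then used to predict a full city field with
# OOB prediction bounds.

road_types <- c("highway", "major", "secondary", "local")

#' Multi-radius buffer predictors around points
#'
#' For each point and buffer radius, computes the clipped road length and
#' traffic load (length x vehicle density, light and heavy separately) per
#' road type, land-cover class percentages, resident population and
#' traffic-light counts; plus point-level distances to the nearest major
#' road, highway, airport and port, and raster lookups (elevation,
#' imperviousness, night lights). Road clipping is exact chord geometry;
#' land-cover and population are aggregated over raster cell centroids
#' within the radius (nearest-cell fallback below the raster resolution).
#'
#' @param points Tibble with `point_id`, `x`, `y` (metres, planar CRS).
#' @param city A `synthetic_city`, or any list with components `roads`,
#'   `grid`, `rasters`, `traffic_lights`, `poi` in the same planar CRS.
#' @param radii Buffer radii in metres (default 20, 50, 100, 300, 500, 1000).
#' @return A tibble, one row per point: `point_id` plus predictor columns
#'   `road_len_<type>_<r>`, `tload_light_<type>_<r>`,
#'   `tload_heavy_<type>_<r>`, `lc_<class>_<r>` (percent), `pop_<r>`,
#'   `lights_<r>`, `dist_major_road`, `dist_highway`, `dist_airport`,
#'   `dist_port`, `elevation`, `imperviousness`, `night_lights`.
#' @export
compute_buffer_predictors <- function(points, city,
                                      radii = c(20, 50, 100, 300, 500, 1000)) {
  for (layer in c("roads", "grid", "rasters", "traffic_lights", "poi"))
    if (is.null(city[[layer]]) || nrow(city[[layer]]) == 0)
      abort(paste0("missing or empty layer: ", layer), class = "no2_lurf_error")
  roads <- city$roads
  grid <- city$grid
  rasters <- dplyr::left_join(city$rasters,
                              grid[, c("cell_id", "x", "y")], by = "cell_id")
  lights <- city$traffic_lights
  poi <- city$poi
  classes <- sort(unique(rasters$landcover))

  n <- nrow(points)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    px <- points$x[i]
    py <- points$y[i]
    vals <- list(point_id = points$point_id[i])

    cell_d2 <- (rasters$x - px)^2 + (rasters$y - py)^2
    light_d2 <- (lights$x - px)^2 + (lights$y - py)^2

    for (r in radii) {
      suf <- paste0("_", r)
      clip <- segment_circle_length(roads$x1, roads$y1, roads$x2, roads$y2,
                                    px, py, r)
      for (tp in road_types) {
        sel <- roads$type == tp
        vals[[paste0("road_len_", tp, suf)]] <- sum(clip[sel])
        vals[[paste0("tload_light_", tp, suf)]] <-
          sum(clip[sel] * roads$density_light[sel])
        vals[[paste0("tload_heavy_", tp, suf)]] <-
          sum(clip[sel] * roads$density_heavy[sel])
      }
      inside <- cell_d2 <= r^2
      if (!any(inside)) inside <- cell_d2 == min(cell_d2)
      for (cl in classes)
        vals[[paste0("lc_", cl, suf)]] <-
          100 * mean(rasters$landcover[inside] == cl)
      vals[[paste0("pop", suf)]] <- sum(rasters$population[cell_d2 <= r^2])
      vals[[paste0("lights", suf)]] <- sum(light_d2 <= r^2)
    }

    dist_to_type <- function(tp) {
      sel <- roads$type == tp
      if (!any(sel)) return(NA_real_)
      min(point_segment_distance(px, py, roads$x1[sel], roads$y1[sel],
                                 roads$x2[sel], roads$y2[sel]))
    }
    vals$dist_major_road <- dist_to_type("major")
    vals$dist_highway <- dist_to_type("highway")
    vals$dist_airport <- sqrt(min((poi$x[poi$kind == "airport"] - px)^2 +
                                    (poi$y[poi$kind == "airport"] - py)^2))
    vals$dist_port <- sqrt(min((poi$x[poi$kind == "port"] - px)^2 +
                                 (poi$y[poi$kind == "port"] - py)^2))
    nearest <- which.min(cell_d2)
    vals$elevation <- rasters$elevation[nearest]
    vals$imperviousness <- rasters$imperviousness[nearest]
    vals$night_lights <- rasters$night_lights[nearest]
    rows[[i]] <- tibble::as_tibble(vals)
  }
  dplyr::bind_rows(rows)
}

#' Fit a Land Use Random Forest
#'
#' Regression forest of annual NO2 estimates at sampler points on the buffer
#' predictor table. One independent model is fit per (city, scenario).
#'
#' @param estimates Tibble with `sampler_id` and `annual_no2` (from
#'   [annualize()]).
#' @param predictors Buffer predictor table whose `point_id` matches
#'   `sampler_id`.
#' @param n_trees,mtry,min_node_size,seed As in [fit_monthly_model()].
#' @param min_points Minimum number of training points (default 30).
#' @return A `forest_fit` with kind `"lurf"`.
#' @export
fit_lurf <- function(estimates, predictors, n_trees = 500, mtry = NULL,
                     min_node_size = 5, seed = 1L, min_points = 30) {
  joined <- dplyr::inner_join(
    dplyr::select(estimates, "sampler_id", "annual_no2"),
    predictors, by = c("sampler_id" = "point_id"))
  if (nrow(joined) < min_points)
    abort(sprintf("need >= %d matched training points, got %d.",
                  min_points, nrow(joined)), class = "no2_lurf_error")
  if (sd(joined$annual_no2) == 0)
    abort("response is constant; forest cannot be fit.",
          class = "no2_lurf_error")
  frame <- dplyr::select(joined, -"sampler_id")
  names(frame)[names(frame) == "annual_no2"] <- "no2"
  cc <- stats::complete.cases(frame)
  if (sum(!cc) > 0)
    inform(sprintf("dropping %d points with missing predictors", sum(!cc)))
  frame <- frame[cc, ]
  p <- ncol(frame) - 1L
  mtry <- mtry %||% ceiling(p / 3)
  model <- ranger::ranger(
    no2 ~ ., data = frame, num.trees = n_trees, mtry = mtry,
    min.node.size = min_node_size, seed = seed, importance = "impurity"
  )
  new_forest_fit(model, joined[cc, ], frame, kind = "lurf")
}

#' Predict the annual NO2 field on a city grid
#'
#' Applies a fitted LURF to the grid predictor table and attaches OOB
#' prediction bounds.
#'
#' @param fit A `forest_fit` from [fit_lurf()].
#' @param grid_predictors Buffer predictor table for the grid centroids
#'   (`point_id` = cell id); columns must match the training predictors.
#' @param alpha Miscoverage level for the OOB interval (default 0.05).
#' @param scenario Scenario label stored on the result.
#' @return A `grid_field` tibble: `cell_id`, `no2`, `no2_lo`, `no2_hi`.
#' @export
predict_grid <- function(fit, grid_predictors, alpha = 0.05, scenario = "S1") {
  stopifnot(inherits(fit, "forest_fit"))
  missing_cols <- setdiff(fit$predictor_names, names(grid_predictors))
  if (length(missing_cols) > 0)
    abort(paste0("grid predictors lack training columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "no2_lurf_error")
  pred <- predict(fit$model,
                  data = grid_predictors[, fit$predictor_names])$predictions
  out <- tibble::tibble(cell_id = grid_predictors$point_id,
                        point = pred)
  out <- oob_interval(fit, out, alpha)
  field <- tibble::tibble(cell_id = out$cell_id, no2 = out$point,
                          no2_lo = out$lower, no2_hi = out$upper)
  attr(field, "scenario") <- scenario
  class(field) <- c("grid_field", class(field))
  field
}

#' Distribution statistics of a predicted field
#'
#' @param field A `grid_field` (or any tibble with an `no2` column).
#' @param column Which column to summarize (default `"no2"`).
#' @return One-row tibble: `n_cells`, `mean`, `sd`, `p5`, `p25`, `p50`,
#'   `p75`, `p95`.
#' @export
summarize_field <- function(field, column = "no2") {
  v <- field[[column]]
  if (length(v) == 0) abort("empty field.", class = "no2_lurf_error")
  q <- quantile(v, c(0.05, 0.25, 0.5, 0.75, 0.95), type = 7, names = FALSE)
  tibble::tibble(n_cells = length(v), mean = mean(v), sd = sd(v),
                 p5 = q[1], p25 = q[2], p50 = q[3], p75 = q[4], p95 = q[5])
}

#' Relative change between two quantities, in percent
#'
#' `100 * (to - from) / from`; used for the scenario shift of city-mean
#' fields and of attributable-death totals.
#'
#' @param from,to Numeric scalars or vectors.
#' @return Percent change.
#' @export
relative_change <- function(from, to) {
  100 * (to - from) / from
}
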