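# minimal hand-built city layers for geometric oracles
toy_city <- function(road_y = 0, density_light = 1000, density_heavy = 100) {
  grid <- tibble::tibble(cell_id = 1:4,
                         x = c(-500, 500, -500, 500), y = c(-500, -500, 500, 500),
                         xmin = x - 500, xmax = x + 500,
                         ymin = y - 500, ymax = y + 500)
  list(
    roads = tibble::tibble(road_id = "R1", type = "major",
                           x1 = -5000, y1 = road_y, x2 = 5000, y2 = road_y,
                           density_light = density_light,
                           density_heavy = density_heavy),
    grid = grid,
    rasters = tibble::tibble(cell_id = 1:4, population = c(10, 20, 30, 40),
                             elevation = 100, imperviousness = 50,
                             night_lights = 10,
                             landcover = rep("urban_fabric", 4)),
    traffic_lights = tibble::tibble(light_id = "T1", x = 0, y = 2000),
    poi = tibble::tibble(kind = c("airport", "port"),
                         x = c(9000, -9000), y = c(0, 0)))
}

test_that("a straight road through the point yields chord length 2r and load 2rd", {
  city <- toy_city(road_y = 0)
  pt <- tibble::tibble(point_id = "P", x = 0, y = 0)
  pr <- compute_buffer_predictors(pt, city, radii = c(20, 100, 1000))
  for (r in c(20, 100, 1000)) {
    expect_equal(pr[[paste0("road_len_major_", r)]], 2 * r, tolerance = 0.01)
    expect_equal(pr[[paste0("tload_light_major_", r)]], 2 * r * 1000,
                 tolerance = 0.01)
    expect_equal(pr[[paste0("tload_heavy_major_", r)]], 2 * r * 100,
                 tolerance = 0.01)
  }
  expect_equal(pr$dist_major_road, 0)
})

test_that("offset roads produce the exact circle-chord length", {
  # road at distance d from the point: chord = 2*sqrt(r^2 - d^2)
  for (d in c(50, 200, 700)) {
    city <- toy_city(road_y = d)
    pt <- tibble::tibble(point_id = "P", x = 0, y = 0)
    pr <- compute_buffer_predictors(pt, city, radii = c(1000))
    expect_equal(pr$road_len_major_1000, 2 * sqrt(1000^2 - d^2),
                 tolerance = 1e-6)
    expect_equal(pr$dist_major_road, d)
  }
  # far beyond every buffer: all road columns zero
  far <- toy_city(road_y = 5000)
  prf <- compute_buffer_predictors(tibble::tibble(point_id = "P", x = 0, y = 0),
                                   far, radii = c(20, 1000))
  expect_equal(prf$road_len_major_20, 0)
  expect_equal(prf$road_len_major_1000, 0)
  expect_equal(prf$tload_light_major_1000, 0)
})

test_that("cumulative buffer quantities are monotone in the radius", {
  city <- cached_city()
  pts <- tibble::tibble(point_id = as.character(1:10),
                        x = runif(10, 0, 1500), y = runif(10, 0, 1500))
  radii <- c(20, 50, 100, 300, 500, 1000)
  pr <- compute_buffer_predictors(pts, city, radii)
  cum_vars <- c(paste0("road_len_", c("highway", "major", "secondary", "local")),
                "pop", "lights")
  for (v in cum_vars) {
    m <- as.matrix(pr[, paste0(v, "_", radii)])
    expect_true(all(diff(t(m)) >= -1e-9), info = v)
  }
})

test_that("uniform land cover gives 100 percent for that class", {
  city <- toy_city()
  pr <- compute_buffer_predictors(tibble::tibble(point_id = "P", x = 0, y = 0),
                                  city, radii = c(100, 1000))
  expect_equal(pr$lc_urban_fabric_100, 100)
  expect_equal(pr$lc_urban_fabric_1000, 100)
})

test_that("LURF ranks traffic variables on top for a traffic-driven field", {
  city <- cached_city()
  # noise-free response: the true annual field at each sampler's cell
  truth <- city$truth$cells$true_s1[match(city$samplers$cell_id,
                                          city$grid$cell_id)]
  est <- tibble::tibble(sampler_id = city$samplers$sampler_id,
                        annual_no2 = truth)
  pts <- tibble::tibble(point_id = city$samplers$sampler_id,
                        x = city$samplers$x, y = city$samplers$y)
  pr <- compute_buffer_predictors(pts, city)
  fit <- fit_lurf(est, pr, n_trees = 300, seed = 8)
  top <- tidy(fit)$variable[1:5]
  expect_true(any(grepl("tload|road_len|dist_highway|dist_major", top)))

  # null response has no spatial signal
  null_est <- dplyr::mutate(est, annual_no2 = rnorm(dplyr::n(), 30, 5))
  null_fit <- fit_lurf(null_est, pr, n_trees = 300, seed = 8)
  expect_lte(null_fit$fit_stats$oob_r2, 0.1)
})

test_that("grid predictions stay inside the training response range and recover the field", {
  city <- cached_city()
  truth <- city$truth$cells$true_s1[match(city$samplers$cell_id,
                                          city$grid$cell_id)]
  est <- tibble::tibble(sampler_id = city$samplers$sampler_id,
                        annual_no2 = truth * exp(rnorm(length(truth), 0, 0.05)))
  pts <- tibble::tibble(point_id = city$samplers$sampler_id,
                        x = city$samplers$x, y = city$samplers$y)
  pr <- compute_buffer_predictors(pts, city)
  fit <- fit_lurf(est, pr, n_trees = 300, seed = 8)
  gp <- tibble::tibble(point_id = as.character(city$grid$cell_id),
                       x = city$grid$x, y = city$grid$y)
  field <- predict_grid(fit, compute_buffer_predictors(gp, city),
                        scenario = "S1")
  expect_true(all(field$no2 >= min(est$annual_no2) &
                    field$no2 <= max(est$annual_no2)))
  expect_true(all(field$no2_lo <= field$no2_hi))
  expect_gt(cor(field$no2, city$truth$cells$true_s1), 0.6)

  expect_error(predict_grid(fit, dplyr::select(compute_buffer_predictors(gp, city),
                                               -dplyr::starts_with("pop"))),
               class = "no2_lurf_error")
})

test_that("shrinkage: lower values over-, higher values under-predicted on noisy data", {
  city <- cached_city()
  truth <- city$truth$cells$true_s1[match(city$samplers$cell_id,
                                          city$grid$cell_id)]
  set.seed(30)
  # heteroscedastic noise growing with the signal
  obs <- truth + rnorm(length(truth), 0, 0.15 * truth)
  est <- tibble::tibble(sampler_id = city$samplers$sampler_id,
                        annual_no2 = obs)
  pts <- tibble::tibble(point_id = city$samplers$sampler_id,
                        x = city$samplers$x, y = city$samplers$y)
  fit <- fit_lurf(est, compute_buffer_predictors(pts, city),
                  n_trees = 300, seed = 8)
  ok <- is.finite(fit$oob_predictions)
  pred <- fit$oob_predictions[ok]
  y <- pred + fit$oob_errors
  lower <- y <= quantile(y, 1 / 3)
  upper <- y >= quantile(y, 2 / 3)
  expect_gt(mean(pred[lower] - y[lower]), 0)
  expect_lt(mean(pred[upper] - y[upper]), 0)
})

test_that("field summaries and relative changes match hand arithmetic", {
  const <- tibble::tibble(no2 = rep(4.2, 10))
  s <- summarize_field(const)
  expect_equal(s$mean, 4.2)
  expect_equal(s$sd, 0)
  expect_equal(unlist(s[, c("p5", "p25", "p50", "p75", "p95")]),
               rep(4.2, 5), ignore_attr = TRUE)
  expect_equal(round(relative_change(29.5, 33.5), 1), 13.6)
  expect_equal(round(relative_change(29.3, 34.6), 1), 18.1)
})
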