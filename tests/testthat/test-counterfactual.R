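# builds a station-month table with a controllable response
sim_training <- function(response = c("linear", "noise"), n_stations = 10,
                         years = 2016:2019, sd = 0, seed = 1) {
  response <- match.arg(response)
  set.seed(seed)
  d <- tidyr::expand_grid(station_id = sprintf("ST%02d", 1:n_stations),
                          year = years, month = 1:12)
  n <- nrow(d)
  d$dew_point <- rnorm(n, 8, 4)
  d$temperature <- 13 - 9 * cos(2 * pi * (d$month - 1) / 12) + rnorm(n, 0, 2)
  d$pressure_sea_level <- rnorm(n, 1015, 5)
  d$rain_cum <- pmax(0, rnorm(n, 60, 25))
  d$wind_dir <- runif(n, 0, 360)
  d$wind_speed <- pmax(0.2, rnorm(n, 2.5, 0.8))
  d$no2 <- switch(response,
    linear = 30 + 2 * d$temperature + rnorm(n, 0, sd),
    noise = rnorm(n, 30, 5))
  d
}

test_that("fit statistics match closed-form expectations", {
  obs <- c(3, 7, 11, 19, 2)
  fs <- compute_fit_stats(obs, obs)
  expect_equal(fs$pred_r2, 1)
  expect_equal(fs$rmspe, 0)
  expect_equal(fs$intercept, 0)
  expect_equal(fs$slope, 1)

  fs2 <- compute_fit_stats(obs, obs + 5)
  expect_equal(fs2$rmspe, 5)
  expect_equal(fs2$slope, 1)
  expect_equal(fs2$intercept, -5)

  expect_error(compute_fit_stats(c(1, 2, 3), c(2, 2, 2)),
               class = "no2_model_error")
  expect_error(compute_fit_stats(1:2, 1:2), class = "no2_model_error")
})

test_that("forest recovers a strong linear signal and not pure noise", {
  strong <- fit_monthly_model(sim_training("linear", n_stations = 8),
                              n_trees = 500, seed = 5)
  expect_gt(strong$fit_stats$oob_r2, 0.9)

  null_r2 <- vapply(1:3, function(s) {
    fit_monthly_model(sim_training(response = "noise", n_stations = 6,
                                   seed = s),
                      n_trees = 200, seed = s)$fit_stats$oob_r2
  }, numeric(1))
  expect_lte(mean(null_r2), 0.1)
})

test_that("fitting is reproducible at a fixed seed and errors on degenerate input", {
  tr <- sim_training("linear", n_stations = 5, sd = 3)
  f1 <- fit_monthly_model(tr, n_trees = 100, seed = 9)
  f2 <- fit_monthly_model(tr, n_trees = 100, seed = 9)
  expect_equal(f1$fit_stats, f2$fit_stats)

  const <- tr
  const$no2 <- 20
  expect_error(fit_monthly_model(const), class = "no2_model_error")
  expect_error(fit_monthly_model(tr[0, ]), class = "no2_model_error")
})

test_that("prediction refuses stations unseen in training, naming them", {
  tr <- sim_training("linear", n_stations = 4, sd = 2)
  fit <- fit_monthly_model(tr, n_trees = 50, seed = 2)
  target <- tr[1:3, ]
  target$station_id <- "ST99"
  expect_error(predict_no_lockdown(fit, target), "ST99",
               class = "no2_model_error")
})

test_that("OOB intervals collapse, stay symmetric, and narrow with alpha", {
  fake <- structure(list(oob_errors = rep(0, 100)), class = "forest_fit")
  pts <- tibble::tibble(point = c(10, 20))
  out <- oob_interval(fake, pts)
  expect_equal(out$lower, pts$point)
  expect_equal(out$upper, pts$point)

  sym <- structure(list(oob_errors = c(-(1:50), 1:50)), class = "forest_fit")
  o2 <- oob_interval(sym, pts, alpha = 0.1)
  expect_equal(o2$point - o2$lower, o2$upper - o2$point, tolerance = 1e-8)
  # one global error distribution: identical width everywhere
  expect_equal(diff(range(o2$upper - o2$lower)), 0)
  # larger alpha never widens
  o3 <- oob_interval(sym, pts, alpha = 0.5)
  expect_true(all(o3$upper - o3$lower <= o2$upper - o2$lower))
  expect_error(oob_interval(sym, pts, alpha = 1.2), class = "no2_model_error")
})

test_that("counterfactual exceeds observed 2020 spring under a real lockdown", {
  city <- cached_city(lockdown_multiplier = 0.6)
  m <- city$stations_monthly
  fit <- fit_monthly_model(dplyr::filter(m, year < 2020),
                           n_trees = 300, seed = 3)
  targets <- dplyr::filter(m, year == 2020, month %in% 3:5)
  pred <- predict_no_lockdown(fit, targets)
  expect_gte(mean(pred$point > targets$no2), 0.9)
})

test_that("with no lockdown the counterfactual is unbiased within 1 ug/m3", {
  # single cities share one spring meteorology anomaly, so the null bias is
  # assessed as a replicate average over independent city realizations
  biases <- vapply(1:6, function(s) {
    city <- generate_city(small_city_config(lockdown_multiplier = 1,
                                            seed = s))
    m <- city$stations_monthly
    fit <- fit_monthly_model(dplyr::filter(m, year < 2020),
                             n_trees = 200, seed = 3)
    targets <- dplyr::filter(m, year == 2020, month %in% 3:5)
    mean(predict_no_lockdown(fit, targets)$point - targets$no2)
  }, numeric(1))
  expect_lt(abs(mean(biases)), 1)
})

test_that("tidy and glance expose importance and fit statistics", {
  fit <- fit_monthly_model(sim_training("linear", n_stations = 5, sd = 2),
                           n_trees = 100, seed = 4)
  td <- tidy(fit)
  expect_true(all(c("variable", "importance") %in% names(td)))
  expect_equal(td$variable[1], "temperature")  # the only true signal
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_true(all(c("oob_r2", "rmse", "pred_r2", "rmspe", "intercept",
                    "slope") %in% names(gl)))
})
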