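# Weather-normalised counterfactual NO2: a random forest trained on
# 2016-2019 station-months (response: monthly mean NO2; predictors:
# meteorology, month, station id) predicts what March-May 2020 would have
# looked like without the lockdown. Uncertainty comes from the empirical
# distribution of out-of-bag (OOB) prediction errors D_i = Y_i - Yhat_i:
# the interval for a new prediction Yhat is
# [Yhat + D_(alpha/2), Yhat + D_(1 - alpha/2)] with empirical quantiles of
# the pooled OOB errors. Tree induction itself is delegated to ranger.

met_predictors <- c("dew_point", "temperature", "pressure_sea_level",
                    "rain_cum", "wind_speed")

# wind direction is circular; encode as sin/cos so 0 and 360 coincide
prepare_rf_frame <- function(data, station_levels = NULL) {
  levels <- station_levels %||% sort(unique(data$station_id))
  unseen <- setdiff(unique(data$station_id), levels)
  if (length(unseen) > 0)
    abort(paste0("station(s) not seen in training: ",
                 paste(unseen, collapse = ", ")),
          class = "no2_model_error")
  tibble::tibble(
    station = factor(data$station_id, levels = levels),
    month = factor(data$month, levels = 1:12),
    dew_point = data$dew_point,
    temperature = data$temperature,
    pressure_sea_level = data$pressure_sea_level,
    rain_cum = data$rain_cum,
    wind_speed = data$wind_speed,
    wind_u = sin(data$wind_dir * pi / 180),
    wind_v = cos(data$wind_dir * pi / 180)
  )
}

#' Fit the monthly weather-normalisation random forest
#'
#' Trains a regression forest of monthly mean NO2 on meteorology (dew point,
#' temperature, sea-level pressure, cumulative rain, wind speed, wind
#' direction as a sin/cos pair), calendar month, and station id, normally on
#' 2016-2019 data. Rows with missing covariates are dropped with a message.
#'
#' @param training Tibble with `station_id`, `year`, `month`, `no2` and the
#'   meteorological columns `dew_point`, `temperature`,
#'   `pressure_sea_level`, `rain_cum`, `wind_dir`, `wind_speed`.
#' @param n_trees,mtry,min_node_size Forest hyperparameters; `mtry` defaults
#'   to one third of the predictors (rounded up).
#' @param seed Integer seed for the forest.
#' @return A `forest_fit` object: the ranger model, per-row OOB predictions
#'   and errors, hyperparameters and fitting statistics (OOB R2, RMSE, and
#'   observed-vs-OOB-predicted R2, RMSPE, intercept, slope).
#' @export
fit_monthly_model <- function(training, n_trees = 500, mtry = NULL,
                              min_node_size = 5, seed = 1L) {
  req <- c("station_id", "year", "month", "no2", met_predictors, "wind_dir")
  missing_cols <- setdiff(req, names(training))
  if (length(missing_cols) > 0)
    abort(paste0("training data lacks columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "no2_model_error")
  cc <- stats::complete.cases(training[, req])
  if (sum(!cc) > 0)
    inform(sprintf("dropping %d station-months with missing values", sum(!cc)))
  training <- training[cc, ]
  if (nrow(training) == 0)
    abort("empty training set.", class = "no2_model_error")
  if (length(unique(training$station_id)) < 2)
    abort("need at least 2 stations.", class = "no2_model_error")
  if (sd(training$no2) == 0)
    abort("response is constant; forest cannot be fit.",
          class = "no2_model_error")
  frame <- prepare_rf_frame(training)
  frame$no2 <- training$no2
  p <- ncol(frame) - 1L
  mtry <- mtry %||% ceiling(p / 3)
  model <- ranger::ranger(
    no2 ~ ., data = frame, num.trees = n_trees, mtry = mtry,
    min.node.size = min_node_size, seed = seed,
    importance = "impurity", respect.unordered.factors = "order"
  )
  new_forest_fit(model, training, frame, kind = "counterfactual",
                 station_levels = levels(frame$station))
}

new_forest_fit <- function(model, training, frame, kind, station_levels = NULL) {
  oob <- model$predictions
  y <- frame$no2
  ok <- is.finite(oob)
  d <- y[ok] - oob[ok]
  fit_stats <- c(
    list(oob_r2 = model$r.squared, rmse = sqrt(mean(d^2))),
    compute_fit_stats(y[ok], oob[ok])
  )
  structure(list(
    model = model,
    training = training,
    station_levels = station_levels,
    predictor_names = setdiff(names(frame), "no2"),
    oob_predictions = oob,
    oob_errors = d,
    hyperparameters = list(n_trees = model$num.trees, mtry = model$mtry,
                           min_node_size = model$min.node.size),
    fit_stats = fit_stats,
    kind = kind
  ), class = "forest_fit")
}

#' Agreement statistics between observed and predicted values
#'
#' `pred_r2` is the squared Pearson correlation; `rmspe` the root mean
#' squared difference; `intercept` and `slope` come from the ordinary least
#' squares regression of observed on predicted.
#'
#' @param observed,predicted Numeric vectors of equal length >= 3 (ug/m3).
#' @return List with `pred_r2`, `rmspe`, `intercept`, `slope`.
#' @export
compute_fit_stats <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 3)
    abort("observed and predicted must have equal length >= 3.",
          class = "no2_model_error")
  if (sd(predicted) == 0)
    abort("predicted values have zero variance; slope undefined.",
          class = "no2_model_error")
  fit <- lm(observed ~ predicted)
  list(
    pred_r2 = cor(observed, predicted)^2,
    rmspe = sqrt(mean((observed - predicted)^2)),
    intercept = unname(coef(fit)[1]),
    slope = unname(coef(fit)[2])
  )
}

#' Predict no-lockdown NO2 for new station-months
#'
#' Applies the fitted weather-normalisation forest to target rows (normally
#' March-May 2020 with the meteorology actually observed then). Target
#' stations must have appeared in training, since station id is a predictor.
#'
#' @param fit A `forest_fit` from [fit_monthly_model()].
#' @param target_rows Tibble with the same predictor columns as training.
#' @return The input tibble with a `point` column of predictions (ug/m3).
#' @export
predict_no_lockdown <- function(fit, target_rows) {
  stopifnot(inherits(fit, "forest_fit"))
  frame <- prepare_rf_frame(target_rows, fit$station_levels)
  pred <- predict(fit$model, data = frame)$predictions
  out <- target_rows
  out$point <- pred
  out
}

#' Out-of-bag prediction intervals
#'
#' Attaches `[point + D_(alpha/2), point + D_(1-alpha/2)]` to each
#' prediction, where D are the pooled OOB errors of the fit and quantiles
#' use linear interpolation of order statistics. One global error
#' distribution is used, so the interval width is the same for every
#' prediction point.
#'
#' @param fit A `forest_fit`.
#' @param points Tibble with a `point` column (from [predict_no_lockdown()]
#'   or grid prediction).
#' @param alpha Miscoverage level in (0, 1); default 0.05.
#' @return The tibble with `lower` and `upper` columns and an `alpha`
#'   attribute.
#' @export
oob_interval <- function(fit, points, alpha = 0.05) {
  stopifnot(inherits(fit, "forest_fit"))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    abort("`alpha` must lie in (0, 1).", class = "no2_model_error")
  if (length(fit$oob_errors) == 0)
    abort("fit has no OOB errors.", class = "no2_model_error")
  qd <- quantile(fit$oob_errors, c(alpha / 2, 1 - alpha / 2),
                 type = 7, names = FALSE)
  points$lower <- points$point + qd[1]
  points$upper <- points$point + qd[2]
  attr(points, "alpha") <- alpha
  points
}

#' @export
print.forest_fit <- function(x, ...) {
  fs <- x$fit_stats
  cat(sprintf("<forest_fit> (%s) %d trees, mtry %d, min node %d, %d rows\n",
              x$kind, x$hyperparameters$n_trees, x$hyperparameters$mtry,
              x$hyperparameters$min_node_size, nrow(x$training)))
  cat(sprintf("  OOB R2 %.3f, RMSE %.2f; pred R2 %.3f, RMSPE %.2f, intercept %.2f, slope %.3f\n",
              fs$oob_r2, fs$rmse, fs$pred_r2, fs$rmspe, fs$intercept, fs$slope))
  invisible(x)
}

#' Tidy a fitted forest: variable importance
#'
#' @param x A `forest_fit`.
#' @param ... Unused.
#' @return Tibble with `variable` and `importance` (impurity), sorted
#'   descending.
#' @export
tidy.forest_fit <- function(x, ...) {
  imp <- ranger::importance(x$model)
  tibble::tibble(variable = names(imp), importance = unname(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' One-row summary of forest fitting statistics
#'
#' @param x A `forest_fit`.
#' @param ... Unused.
#' @return One-row tibble with `oob_r2`, `rmse`, `pred_r2`, `rmspe`,
#'   `intercept`, `slope`, `n`.
#' @export
glance.forest_fit <- function(x, ...) {
  fs <- x$fit_stats
  tibble::tibble(oob_r2 = fs$oob_r2, rmse = fs$rmse, pred_r2 = fs$pred_r2,
                 rmspe = fs$rmspe, intercept = fs$intercept,
                 slope = fs$slope, n = nrow(x$training))
}
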