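# Pipeline orchestration and file I/O: a stage-per-function runner tying
# together generation, QC, counterfactual modelling, annualization, spatial
# prediction and the HIA, with text artifacts (CSV/JSON) carrying a config
# hash and seed for provenance.

#' Pipeline configuration
#'
#' Bundles the synthetic-city configuration, QC options, forest
#' hyperparameters, buffer radii, the campaign window and the dose-response
#' parameters.
#'
#' @param city A [city_config()].
#' @param accuracy_factor Passive/reference accuracy factor applied in QC
#'   (default 0.92).
#' @param direction Accuracy correction direction, `"divide"` or
#'   `"multiply"`.
#' @param window Campaign window (closed Date interval).
#' @param rf,lurf Lists of forest hyperparameters (`n_trees`, `mtry`,
#'   `min_node_size`, `seed`).
#' @param radii Buffer radii in metres.
#' @param alpha Miscoverage level for OOB intervals.
#' @param hia A [hia_params()].
#' @param uncertainty If `TRUE`, run the min/max-factor, counterfactual
#'   interval and grid-interval variants.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(city = city_config(),
                            accuracy_factor = 0.92,
                            direction = c("divide", "multiply"),
                            window = as.Date(c("2020-02-08", "2020-03-07")),
                            rf = list(n_trees = 500, mtry = NULL,
                                      min_node_size = 5, seed = 11L),
                            lurf = list(n_trees = 500, mtry = NULL,
                                        min_node_size = 5, seed = 12L),
                            radii = c(20, 50, 100, 300, 500, 1000),
                            alpha = 0.05,
                            hia = hia_params(),
                            uncertainty = TRUE) {
  direction <- match.arg(direction)
  structure(list(city = city, accuracy_factor = accuracy_factor,
                 direction = direction, window = window, rf = rf,
                 lurf = lurf, radii = radii, alpha = alpha, hia = hia,
                 uncertainty = uncertainty),
            class = "pipeline_config")
}

config_hash <- function(config) rlang::hash(unclass(config))

#' Run the full pipeline in memory
#'
#' Executes generate, qc, counterfactual, annualize, lurf and hia in order
#' and returns all intermediate and final results. Deterministic given the
#' seeds in the configuration.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_result` list; see the components in the source or
#'   the vignette.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  city <- generate_city(config$city)

  qc <- qc_samplers(city$samplers, city$boundary,
                    factor = config$accuracy_factor,
                    direction = config$direction)

  training <- dplyr::filter(city$stations_monthly, .data$year < 2020)
  targets <- dplyr::filter(city$stations_monthly, .data$year == 2020,
                           .data$month %in% 3:5)
  cf_fit <- fit_monthly_model(training, n_trees = config$rf$n_trees,
                              mtry = config$rf$mtry,
                              min_node_size = config$rf$min_node_size,
                              seed = config$rf$seed)
  cf_pred <- predict_no_lockdown(cf_fit, targets)
  cf_pred <- oob_interval(cf_fit, cf_pred, config$alpha)

  daily <- city$stations_daily_2020
  window_means <- campaign_window_mean(daily, config$window)
  monthly_obs <- monthly_means_from_daily(daily)
  annual_s1 <- annual_mean_from_monthly(monthly_obs)
  annual_s2 <- compose_counterfactual_annual(monthly_obs, cf_pred)
  factors_s1 <- adjustment_factors(window_means, annual_s1, "S1",
                                   config$city$city_name)
  factors_s2 <- adjustment_factors(window_means, annual_s2, "S2",
                                   config$city$city_name)
  est_s1 <- annualize(qc$samplers, factors_s1)
  est_s2 <- annualize(qc$samplers, factors_s2)

  sampler_points <- tibble::tibble(point_id = qc$samplers$sampler_id,
                                   x = qc$samplers$x, y = qc$samplers$y)
  grid_points <- tibble::tibble(point_id = as.character(city$grid$cell_id),
                                x = city$grid$x, y = city$grid$y)
  pred_samplers <- compute_buffer_predictors(sampler_points, city,
                                             config$radii)
  pred_grid <- compute_buffer_predictors(grid_points, city, config$radii)

  fit_field <- function(est, scenario, seed, column = "annual_no2") {
    est2 <- est
    est2$annual_no2 <- est[[column]]
    fit <- fit_lurf(est2[, c("sampler_id", "annual_no2")], pred_samplers,
                    n_trees = config$lurf$n_trees, mtry = config$lurf$mtry,
                    min_node_size = config$lurf$min_node_size, seed = seed)
    list(fit = fit,
         field = predict_grid(fit, pred_grid, config$alpha, scenario))
  }
  l1 <- fit_field(est_s1, "S1", config$lurf$seed)
  l2 <- fit_field(est_s2, "S2", config$lurf$seed + 1L)

  grid <- city$grid
  blocks <- city$blocks
  link <- function(field, column = "no2") {
    bl <- link_blocks_to_grid(blocks, field, grid, column = column)
    bl
  }
  blocks_s1 <- link(l1$field)
  blocks_s2 <- link(l2$field)
  hia_s1 <- block_hia(blocks_s1, config$hia, "S1")
  hia_s2 <- block_hia(blocks_s2, config$hia, "S2")
  delta <- scenario_delta(hia_s1$city, hia_s2$city)
  districts_s1 <- aggregate_districts(hia_s1$blocks)
  districts_s2 <- aggregate_districts(hia_s2$blocks)

  uncertainty <- NULL
  if (isTRUE(config$uncertainty)) {
    variant_field_blocks <- function(est, column, scenario, seed) {
      link(fit_field(est, scenario, seed, column = column)$field)
    }
    # (a) min/max annual adjustment factors: alternative complete runs
    v_fac_s1 <- list(
      lo = variant_field_blocks(est_s1, "annual_no2_lo", "S1",
                                config$lurf$seed),
      hi = variant_field_blocks(est_s1, "annual_no2_hi", "S1",
                                config$lurf$seed))
    v_fac_s2 <- list(
      lo = variant_field_blocks(est_s2, "annual_no2_lo", "S2",
                                config$lurf$seed + 1L),
      hi = variant_field_blocks(est_s2, "annual_no2_hi", "S2",
                                config$lurf$seed + 1L))
    # (b) counterfactual monthly prediction interval (S2 only)
    rf_variant <- function(bound) {
      p <- cf_pred
      p$point <- p[[bound]]
      a2 <- compose_counterfactual_annual(monthly_obs, p)
      f2 <- adjustment_factors(window_means, a2, "S2",
                               config$city$city_name)
      e2 <- annualize(qc$samplers, f2)
      variant_field_blocks(e2, "annual_no2", "S2", config$lurf$seed + 1L)
    }
    v_rf_s2 <- list(lo = rf_variant("lower"), hi = rf_variant("upper"))
    # (c) LURF grid OOB bounds
    v_grid_s1 <- list(lo = link(l1$field, "no2_lo"),
                      hi = link(l1$field, "no2_hi"))
    v_grid_s2 <- list(lo = link(l2$field, "no2_lo"),
                      hi = link(l2$field, "no2_hi"))
    uncertainty <- list(
      S1 = uncertainty_ledger(blocks_s1,
                              list(adjustment_factors = v_fac_s1,
                                   lurf_oob = v_grid_s1),
                              config$hia, "S1"),
      S2 = uncertainty_ledger(blocks_s2,
                              list(adjustment_factors = v_fac_s2,
                                   rf_interval = v_rf_s2,
                                   lurf_oob = v_grid_s2),
                              config$hia, "S2"))
  }

  structure(list(
    config = config, city = city, qc = qc,
    counterfactual = list(fit = cf_fit, predictions = cf_pred),
    window_means = window_means, monthly_obs = monthly_obs,
    annual_means = list(S1 = annual_s1, S2 = annual_s2),
    factors = list(S1 = factors_s1, S2 = factors_s2),
    estimates = list(S1 = est_s1, S2 = est_s2),
    lurf = list(S1 = l1$fit, S2 = l2$fit),
    fields = list(S1 = l1$field, S2 = l2$field),
    hia = list(S1 = hia_s1, S2 = hia_s2),
    districts = list(S1 = districts_s1, S2 = districts_s2),
    delta = delta, uncertainty = uncertainty
  ), class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  factors: S1 %.3f, S2 %.3f\n",
              x$factors$S1$factor_mean, x$factors$S2$factor_mean))
  cat(sprintf("  field means: S1 %.1f, S2 %.1f ug/m3\n",
              mean(x$fields$S1$no2), mean(x$fields$S2$no2)))
  cat(sprintf("  attributable deaths: S1 %.0f, S2 %.0f; prevented %.0f (%+.1f%%)\n",
              x$hia$S1$city$total_attributable,
              x$hia$S2$city$total_attributable,
              x$delta$prevented_deaths, x$delta$pct_change))
  invisible(x)
}

# ---- file-based staging ----------------------------------------------------

write_stage_csv <- function(df, path, config) {
  meta <- c(paste0("# config_hash: ", config_hash(config)),
            paste0("# seed: ", config$city$seed))
  writeLines(meta, path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

read_stage_csv <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

write_stage_json <- function(x, path, config) {
  x$meta <- list(config_hash = config_hash(config),
                 seed = config$city$seed)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

need_artifact <- function(path, producer) {
  if (!file.exists(path))
    abort(paste0("missing artifact '", basename(path),
                 "'; run stage '", producer, "' first."),
          class = "no2_stage_error")
  path
}

#' Run one pipeline stage against a working directory
#'
#' Stages: `generate`, `qc`, `counterfactual`, `annualize`, `lurf`, `hia`,
#' `report`. Each stage reads the text artifacts of its upstream stages
#' from `outdir` and writes its own; a missing upstream artifact raises an
#' error naming the stage that produces it. All CSV artifacts carry a
#' config-hash/seed comment header.
#'
#' @param stage Stage name.
#' @param config A [pipeline_config()].
#' @param outdir Working directory for artifacts.
#' @return Invisibly, the paths written.
#' @export
run_stage <- function(stage = c("generate", "qc", "counterfactual",
                                "annualize", "lurf", "hia", "report"),
                      config = pipeline_config(), outdir) {
  stage <- match.arg(stage)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  written <- switch(stage,
    generate = {
      city <- generate_city(config$city)
      write_stage_csv(city$samplers, p("samplers.csv"), config)
      write_stage_csv(city$boundary, p("boundary.csv"), config)
      write_stage_csv(city$stations_monthly, p("stations_monthly.csv"), config)
      write_stage_csv(city$stations_daily_2020, p("stations_daily_2020.csv"),
                      config)
      write_stage_csv(city$roads, p("roads.csv"), config)
      write_stage_csv(dplyr::left_join(city$rasters,
                                       city$grid[, c("cell_id", "x", "y")],
                                       by = "cell_id"),
                      p("rasters.csv"), config)
      write_stage_csv(city$traffic_lights, p("traffic_lights.csv"), config)
      write_stage_csv(city$poi, p("poi.csv"), config)
      write_stage_csv(city$grid, p("grid.csv"), config)
      write_stage_csv(city$blocks, p("blocks.csv"), config)
      write_stage_json(list(lambda = city$truth$lambda,
                            campaign_factor = city$truth$campaign_factor,
                            true_attributable_s1 = city$truth$true_attributable_s1,
                            true_attributable_s2 = city$truth$true_attributable_s2,
                            true_prevented = city$truth$true_prevented),
                       p("truth.json"), config)
      p(c("samplers.csv", "boundary.csv", "stations_monthly.csv",
          "stations_daily_2020.csv", "grid.csv", "blocks.csv", "truth.json"))
    },
    qc = {
      samplers <- read_stage_csv(need_artifact(p("samplers.csv"), "generate"))
      boundary <- read_stage_csv(need_artifact(p("boundary.csv"), "generate"))
      res <- qc_samplers(samplers, boundary,
                         factor = config$accuracy_factor,
                         direction = config$direction)
      write_stage_csv(res$samplers, p("samplers_qc.csv"), config)
      write_stage_json(unclass(res$report), p("qc_report.json"), config)
      p(c("samplers_qc.csv", "qc_report.json"))
    },
    counterfactual = {
      monthly <- read_stage_csv(need_artifact(p("stations_monthly.csv"),
                                              "generate"))
      fit <- fit_monthly_model(dplyr::filter(monthly, .data$year < 2020),
                               n_trees = config$rf$n_trees,
                               mtry = config$rf$mtry,
                               min_node_size = config$rf$min_node_size,
                               seed = config$rf$seed)
      targets <- dplyr::filter(monthly, .data$year == 2020,
                               .data$month %in% 3:5)
      pred <- oob_interval(fit, predict_no_lockdown(fit, targets),
                           config$alpha)
      write_stage_csv(
        pred[, c("station_id", "year", "month", "point", "lower", "upper")],
        p("counterfactual_predictions.csv"), config)
      write_stage_json(fit$fit_stats, p("fit_stats.json"), config)
      p(c("counterfactual_predictions.csv", "fit_stats.json"))
    },
    annualize = {
      daily <- read_stage_csv(need_artifact(p("stations_daily_2020.csv"),
                                            "generate"))
      pred <- read_stage_csv(need_artifact(p("counterfactual_predictions.csv"),
                                           "counterfactual"))
      sq <- read_stage_csv(need_artifact(p("samplers_qc.csv"), "qc"))
      window_means <- campaign_window_mean(daily, config$window)
      monthly_obs <- monthly_means_from_daily(daily)
      f1 <- adjustment_factors(window_means,
                               annual_mean_from_monthly(monthly_obs),
                               "S1", config$city$city_name)
      f2 <- adjustment_factors(
        window_means, compose_counterfactual_annual(monthly_obs, pred),
        "S2", config$city$city_name)
      est <- dplyr::bind_rows(annualize(sq, f1), annualize(sq, f2))
      write_stage_csv(est, p("annual_estimates.csv"), config)
      write_stage_json(list(
        S1 = list(factor_mean = f1$factor_mean, factor_sd = f1$factor_sd,
                  factor_min = f1$factor_min, factor_max = f1$factor_max),
        S2 = list(factor_mean = f2$factor_mean, factor_sd = f2$factor_sd,
                  factor_min = f2$factor_min, factor_max = f2$factor_max)),
        p("factors.json"), config)
      p(c("annual_estimates.csv", "factors.json"))
    },
    lurf = {
      est <- read_stage_csv(need_artifact(p("annual_estimates.csv"),
                                          "annualize"))
      sq <- read_stage_csv(need_artifact(p("samplers_qc.csv"), "qc"))
      city <- list(
        roads = read_stage_csv(need_artifact(p("roads.csv"), "generate")),
        grid = read_stage_csv(need_artifact(p("grid.csv"), "generate")),
        rasters = read_stage_csv(need_artifact(p("rasters.csv"), "generate")),
        traffic_lights = read_stage_csv(need_artifact(p("traffic_lights.csv"),
                                                      "generate")),
        poi = read_stage_csv(need_artifact(p("poi.csv"), "generate")))
      city$rasters <- dplyr::select(city$rasters, -dplyr::any_of(c("x", "y")))
      sampler_points <- tibble::tibble(point_id = sq$sampler_id,
                                       x = sq$x, y = sq$y)
      grid_points <- tibble::tibble(point_id = as.character(city$grid$cell_id),
                                    x = city$grid$x, y = city$grid$y)
      ps <- compute_buffer_predictors(sampler_points, city, config$radii)
      pg <- compute_buffer_predictors(grid_points, city, config$radii)
      stats <- list()
      for (sc in c("S1", "S2")) {
        e <- dplyr::filter(est, .data$scenario == sc)
        fit <- fit_lurf(e[, c("sampler_id", "annual_no2")], ps,
                        n_trees = config$lurf$n_trees,
                        mtry = config$lurf$mtry,
                        min_node_size = config$lurf$min_node_size,
                        seed = config$lurf$seed + (sc == "S2"))
        field <- predict_grid(fit, pg, config$alpha, sc)
        write_stage_csv(field, p(paste0("grid_field_", sc, ".csv")), config)
        write_stage_csv(tidy(fit), p(paste0("importance_", sc, ".csv")),
                        config)
        stats[[sc]] <- fit$fit_stats
      }
      write_stage_json(stats, p("lurf_stats.json"), config)
      p(c("grid_field_S1.csv", "grid_field_S2.csv", "lurf_stats.json"))
    },
    hia = {
      f1 <- read_stage_csv(need_artifact(p("grid_field_S1.csv"), "lurf"))
      f2 <- read_stage_csv(need_artifact(p("grid_field_S2.csv"), "lurf"))
      grid <- read_stage_csv(need_artifact(p("grid.csv"), "generate"))
      blocks <- read_stage_csv(need_artifact(p("blocks.csv"), "generate"))
      h1 <- block_hia(link_blocks_to_grid(blocks, f1, grid), config$hia, "S1")
      h2 <- block_hia(link_blocks_to_grid(blocks, f2, grid), config$hia, "S2")
      write_stage_csv(dplyr::bind_rows(h1$blocks, h2$blocks),
                      p("hia_blocks.csv"), config)
      write_stage_csv(dplyr::bind_rows(aggregate_districts(h1$blocks),
                                       aggregate_districts(h2$blocks)),
                      p("hia_districts.csv"), config)
      write_stage_json(list(S1 = as.list(h1$city), S2 = as.list(h2$city),
                            delta = as.list(scenario_delta(h1$city, h2$city))),
                       p("hia_city.json"), config)
      p(c("hia_blocks.csv", "hia_districts.csv", "hia_city.json"))
    },
    report = {
      hc <- jsonlite::read_json(need_artifact(p("hia_city.json"), "hia"))
      fs <- jsonlite::read_json(need_artifact(p("factors.json"), "annualize"))
      f1 <- read_stage_csv(need_artifact(p("grid_field_S1.csv"), "lurf"))
      f2 <- read_stage_csv(need_artifact(p("grid_field_S2.csv"), "lurf"))
      s1 <- summarize_field(f1)
      s2 <- summarize_field(f2)
      lines <- c(
        paste0("# Pipeline report: ", config$city$city_name),
        "",
        sprintf("Annual adjustment factors: S1 %.3f, S2 %.3f",
                fs$S1$factor_mean, fs$S2$factor_mean),
        sprintf("Grid mean NO2: S1 %.1f, S2 %.1f ug/m3 (change %+.1f%%)",
                s1$mean, s2$mean, relative_change(s1$mean, s2$mean)),
        sprintf("Attributable deaths: S1 %.0f, S2 %.0f; prevented %.0f (%+.1f%%)",
                hc$S1$total_attributable, hc$S2$total_attributable,
                hc$delta$prevented_deaths, hc$delta$pct_change))
      writeLines(lines, p("report.md"))
      p("report.md")
    }
  )
  invisible(written)
}
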