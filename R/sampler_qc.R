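# Quality control for the passive-sampler campaign: eligibility filters
# (administrative boundary, outdoor placement, mounting height), the strong
# outlier rule x < P25 - 3*IQR | x > P75 + 3*IQR on the pooled measurements,
# and the co-location accuracy calibration against reference stations.

#' Eligibility filter for passive samplers
#'
#' Removes samplers placed outside the administrative boundary, indoors, or
#' mounted below three metres. The rule is strict: `height_m = 3` is kept.
#' Samplers with missing coordinates, indoor flag or height cannot be
#' assessed and are excluded, with their ids listed in the report.
#'
#' @param samplers Tibble with `sampler_id`, `x`, `y`, `indoor`, `height_m`.
#' @param boundary Closed polygon (data frame with `x`, `y`); points on the
#'   edge count as inside.
#' @return List with `samplers` (the kept rows) and `report` (a list of
#'   exclusion counts and any per-sampler metadata errors).
#' @export
filter_eligibility <- function(samplers, boundary) {
  n_input <- nrow(samplers)
  bad_meta <- !stats::complete.cases(
    samplers[, c("x", "y", "indoor", "height_m")])
  meta_errors <- samplers$sampler_id[bad_meta]
  s <- samplers[!bad_meta, ]

  inside <- point_in_polygon(s$x, s$y, boundary)
  n_boundary <- sum(!inside)
  s <- s[inside, ]

  n_indoor <- sum(s$indoor)
  s <- s[!s$indoor, ]

  n_height <- sum(s$height_m < 3)
  s <- s[s$height_m >= 3, ]

  list(
    samplers = s,
    report = list(
      n_input = n_input,
      n_excluded_metadata = length(meta_errors),
      metadata_errors = meta_errors,
      n_excluded_boundary = n_boundary,
      n_excluded_indoor = n_indoor,
      n_excluded_height = n_height
    )
  )
}

#' Strong-outlier mask on a pool of measurements
#'
#' Flags values below `P25 - 3*IQR` or above `P75 + 3*IQR`, with the
#' percentiles computed once on the full input pool (no iteration after
#' removal). Percentiles use the linear-interpolation convention
#' (`quantile(type = 7)`).
#'
#' @param values Numeric vector of concentrations (ug/m3), length >= 4.
#' @return Logical mask, `TRUE` for outliers; percentile bounds are attached
#'   as attributes `p25`, `p75`, `iqr`, `lower`, `upper`.
#' @export
detect_outliers <- function(values) {
  if (length(values) < 4)
    abort("outlier rule needs at least 4 values.", class = "no2_qc_error")
  q <- quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lower <- q[1] - 3 * iqr
  upper <- q[2] + 3 * iqr
  mask <- values < lower | values > upper
  structure(mask, p25 = q[1], p75 = q[2], iqr = iqr,
            lower = lower, upper = upper)
}

#' Accuracy calibration from co-located sampler/station pairs
#'
#' For each reference station with co-located passive samplers, the ratio
#' passive/station is formed; the accuracy factor is the arithmetic mean of
#' those ratios. A factor below 1 means the samplers under-read.
#'
#' @param colocated Tibble (or data frame) with columns `passive_mean` and
#'   `station_mean` (ug/m3), one row per station.
#' @return List with `per_station_ratio` and `factor`.
#' @export
calibrate_accuracy <- function(colocated) {
  if (nrow(colocated) < 1)
    abort("need at least one co-located pair.", class = "no2_qc_error")
  if (any(colocated$station_mean <= 0))
    abort("station means must be positive.", class = "no2_qc_error")
  ratios <- colocated$passive_mean / colocated$station_mean
  list(per_station_ratio = ratios, factor = mean(ratios))
}

#' Apply the accuracy factor to raw sampler values
#'
#' Default direction is `"divide"`: the factor is a passive/reference ratio,
#' so dividing maps the passive values onto the reference scale (a factor of
#' 0.92 raises an under-reading sampler). `"multiply"` is available for the
#' opposite convention.
#'
#' @param samplers Tibble with `no2_raw`.
#' @param factor Positive accuracy factor (default the campaign value 0.92).
#' @param direction `"divide"` (default) or `"multiply"`.
#' @return The tibble with an added `no2_corrected` column.
#' @export
apply_accuracy <- function(samplers, factor = 0.92,
                           direction = c("divide", "multiply")) {
  direction <- match.arg(direction)
  if (!is.numeric(factor) || factor <= 0)
    abort("accuracy factor must be positive.", class = "no2_qc_error")
  samplers$no2_corrected <- switch(direction,
    divide = samplers$no2_raw / factor,
    multiply = samplers$no2_raw * factor
  )
  samplers
}

#' Full sampler QC: eligibility, outlier removal, accuracy correction
#'
#' Filters are applied in the order boundary, indoor, height, outlier, so
#' the outlier percentiles are computed on eligible samples only; each
#' sampler is counted under the first filter that removes it. The accuracy
#' correction is applied to the retained samplers.
#'
#' @inheritParams filter_eligibility
#' @inheritParams apply_accuracy
#' @return List with `samplers` (retained rows, with `no2_corrected`) and
#'   `report` (a `qc_report` list of counts and outlier bounds).
#' @export
qc_samplers <- function(samplers, boundary, factor = 0.92,
                        direction = c("divide", "multiply")) {
  direction <- match.arg(direction)
  elig <- filter_eligibility(samplers, boundary)
  s <- elig$samplers
  mask <- detect_outliers(s$no2_raw)
  n_outlier <- sum(mask)
  s <- s[!mask, ]
  s <- apply_accuracy(s, factor, direction)
  rep0 <- elig$report
  report <- structure(list(
    n_input = rep0$n_input,
    n_excluded_metadata = rep0$n_excluded_metadata,
    metadata_errors = rep0$metadata_errors,
    n_excluded_boundary = rep0$n_excluded_boundary,
    n_excluded_indoor = rep0$n_excluded_indoor,
    n_excluded_height = rep0$n_excluded_height,
    n_excluded_outlier = n_outlier,
    n_final = nrow(s),
    p25 = attr(mask, "p25"), p75 = attr(mask, "p75"),
    iqr = attr(mask, "iqr"),
    lower_bound = attr(mask, "lower"), upper_bound = attr(mask, "upper"),
    accuracy_factor = factor, direction = direction
  ), class = "qc_report")
  list(samplers = s, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat(sprintf("  input: %d; excluded: %d metadata, %d boundary, %d indoor, %d height, %d outlier; final: %d\n",
              x$n_input, x$n_excluded_metadata, x$n_excluded_boundary,
              x$n_excluded_indoor, x$n_excluded_height, x$n_excluded_outlier,
              x$n_final))
  cat(sprintf("  outlier bounds: [%.2f, %.2f] (P25 %.2f, P75 %.2f, IQR %.2f)\n",
              x$lower_bound, x$upper_bound, x$p25, x$p75, x$iqr))
  cat(sprintf("  accuracy factor %.3f (%s)\n", x$accuracy_factor, x$direction))
  invisible(x)
}
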