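# Shared fixtures: a small synthetic city memoised per configuration so the
# heavier model tests reuse one generation.

.city_cache <- new.env(parent = emptyenv())

small_city_config <- function(...) {
  defaults <- list(n_cells_x = 15, n_cells_y = 15, cell_size = 100,
                   n_stations = 12, n_samplers = 120, n_blocks = 25,
                   n_districts = 5, seed = 42L)
  do.call(city_config, utils::modifyList(defaults, list(...)))
}

cached_city <- function(...) {
  cfg <- small_city_config(...)
  key <- paste(deparse(unclass(cfg)), collapse = "")
  if (is.null(.city_cache[[key]]))
    .city_cache[[key]] <- generate_city(cfg)
  .city_cache[[key]]
}

# independent brute-force oracle for the strong-outlier rule: percentiles by
# explicit linear interpolation of sorted order statistics
oracle_outliers <- function(values) {
  s <- sort(values)
  n <- length(s)
  pct <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, n)] - s[lo])
  }
  p25 <- pct(0.25)
  p75 <- pct(0.75)
  iqr <- p75 - p25
  values < p25 - 3 * iqr | values > p75 + 3 * iqr
}

# simple square boundary polygon
square_boundary <- function(side = 1000) {
  tibble::tibble(x = c(0, side, side, 0), y = c(0, 0, side, side))
}
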