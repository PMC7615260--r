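#' Generate the synthetic climate archive
#'
#' Builds a daily reference temperature and precipitation field over the toy
#' geography (the stand-in for a reanalysis archive) plus the generating
#' parameters of a pseudo-GCM ensemble. The reference has a planar spatial
#' climatology (so bilinear regridding is exact by construction), a shared
#' seasonal cycle, per-cell interannual anomalies and day-to-day weather
#' noise, on a 365-day calendar. Each pseudo-GCM is a *warped reference*: it
#' shares the reference's weather realization and adds (i) a per-calendar-
#' month additive bias drawn with SD `gcm_bias_sd` and (ii) a scenario
#' warming ramp, linear in year from 2015, scaled by a per-GCM trend
#' multiplier. The injected biases and trend multipliers are returned as
#' machine-readable truth for downstream diagnostics.
#'
#' @param config a [synth_config()].
#' @return A `synth_climate` list with elements `ref_temperature` and
#'   `ref_precipitation` ([grid_field()]s), `gcm_bias` (tibble: gcm_id,
#'   month, bias_degc), `gcm_trend` (tibble: gcm_id, scenario,
#'   trend_per_decade), `layout` (country rectangles) and `config`.
#' @export
generate_climate <- function(config) {
  validate_synth_config(config)
  if (config$years[2] - config$years[1] < 10L) {
    stop("the climate span must cover at least one decade.", call. = FALSE)
  }
  set.seed(config$seed + 11L)
  layout <- country_layout(config)
  res <- config$grid_resolution
  lon <- seq(min(layout$lon_min) + res / 2, max(layout$lon_max) - res / 2, by = res)
  lat <- seq(min(layout$lat_min) + res / 2, max(layout$lat_max) - res / 2, by = res)
  dates <- daily_axis_noleap(config$years[1], config$years[2])
  nlat <- length(lat); nlon <- length(lon); nday <- length(dates)

  # Planar spatial climatology spanning the configured country-mean range.
  tr <- config$country_temp_range
  slope_lon <- diff(tr) / (max(layout$lon_max) - min(layout$lon_min))
  clim <- outer(0.15 * (lat - mean(lat)), slope_lon * (lon - min(layout$lon_min)),
                "+") + tr[1] + slope_lon * 0 # nlat x nlon
  clim <- clim + (mean(tr) - mean(clim))     # center on the configured range

  yrs <- as.integer(format(dates, "%Y"))
  doy <- stats::ave(rep(1L, nday), yrs, FUN = seq_along) # 1..365 within year
  season <- config$seasonal_amplitude * cos(2 * pi * (doy - 15) / 365)
  year_levels <- sort(unique(yrs))
  anom_year <- matrix(rnorm(nlat * nlon * length(year_levels),
                            sd = config$sd_interannual),
                      nrow = nlat * nlon)
  noise <- matrix(rnorm(nlat * nlon * nday, sd = config$sd_daily),
                  nrow = nlat * nlon)
  tvals <- matrix(rep(as.vector(clim), nday), nrow = nlat * nlon) +
    matrix(rep(season, each = nlat * nlon), nrow = nlat * nlon) +
    anom_year[, match(yrs, year_levels)] + noise
  ref_temp <- grid_field(lat, lon, dates,
                         array(tvals, dim = c(nlat, nlon, nday)),
                         variable = "temperature")

  # Precipitation: wetter at low latitude, gamma daily totals, wet-season peak.
  pmean <- outer(3.5 - 0.2 * abs(lat - mean(lat)), rep(1, nlon)) # mm/day
  pseason <- 1 + 0.5 * sin(2 * pi * (doy - 100) / 365)
  prate <- pmax(matrix(rep(as.vector(pmean), nday), nrow = nlat * nlon) *
                  matrix(rep(pseason, each = nlat * nlon), nrow = nlat * nlon),
                0.05)
  pvals <- rgamma(nlat * nlon * nday, shape = 0.6, scale = as.vector(prate) / 0.6)
  ref_precip <- grid_field(lat, lon, dates,
                           array(pvals, dim = c(nlat, nlon, nday)),
                           variable = "precipitation")

  gcm_ids <- sprintf("gcm%02d", seq_len(config$n_gcms))
  gcm_bias <- tibble::tibble(
    gcm_id = rep(gcm_ids, each = 12L),
    month = rep(1:12, config$n_gcms),
    bias_degc = rnorm(12L * config$n_gcms, sd = config$gcm_bias_sd)
  )
  mult <- pmax(rnorm(config$n_gcms, mean = 1, sd = config$gcm_trend_spread), 0.2)
  gcm_trend <- tidyr::expand_grid(gcm_id = gcm_ids, scenario = config$scenarios)
  gcm_trend$trend_per_decade <-
    config$warming_per_decade[gcm_trend$scenario] * mult[match(gcm_trend$gcm_id, gcm_ids)]

  structure(list(ref_temperature = ref_temp, ref_precipitation = ref_precip,
                 gcm_bias = gcm_bias, gcm_trend = gcm_trend,
                 layout = layout, config = config),
            class = "synth_climate")
}

#' @export
print.synth_climate <- function(x, ...) {
  cat(sprintf("<synth_climate: %d GCMs x %d scenarios, %d-%d, %.3g deg grid>\n",
              x$config$n_gcms, length(x$config$scenarios),
              x$config$years[1], x$config$years[2], x$config$grid_resolution))
  invisible(x)
}

#' Realize one pseudo-GCM daily temperature field
#'
#' Materializes the raw (uncorrected) daily temperature field of one ensemble
#' member under one scenario: the shared reference weather plus that GCM's
#' injected monthly bias and its scenario warming ramp (linear in year from
#' 2015, zero before).
#'
#' @param climate a `synth_climate` from [generate_climate()].
#' @param gcm_id,scenario member and scenario labels.
#' @return A temperature [grid_field()] on the reference grid.
#' @export
realize_gcm <- function(climate, gcm_id, scenario) {
  stopifnot(inherits(climate, "synth_climate"))
  bias <- climate$gcm_bias[climate$gcm_bias$gcm_id == gcm_id, ]
  trend <- climate$gcm_trend[climate$gcm_trend$gcm_id == gcm_id &
                               climate$gcm_trend$scenario == scenario, ]
  if (nrow(bias) != 12L || nrow(trend) != 1L) {
    stop("unknown gcm_id or scenario: ", gcm_id, " / ", scenario, call. = FALSE)
  }
  ref <- climate$ref_temperature
  mon <- as.integer(format(ref$time, "%m"))
  yr <- as.integer(format(ref$time, "%Y"))
  offset <- bias$bias_degc[mon] +
    trend$trend_per_decade / 10 * pmax(yr - 2015L, 0L)
  vals <- ref$values + rep(offset, each = length(ref$lat) * length(ref$lon))
  grid_field(ref$lat, ref$lon, ref$time, vals, variable = "temperature")
}

#' Write the generating truth of a synthetic climate archive
#'
#' Emits the injected per-GCM monthly biases and warming trends (plus the key
#' generator settings) as a YAML sidecar, for use in tests and diagnostics.
#'
#' @param climate a `synth_climate`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_climate_truth_yaml <- function(climate, path) {
  truth <- list(
    seed = climate$config$seed,
    gcm_bias = lapply(split(climate$gcm_bias, climate$gcm_bias$gcm_id),
                      function(d) as.list(setNames(d$bias_degc, month.abb))),
    gcm_trend_per_decade = lapply(
      split(climate$gcm_trend, climate$gcm_trend$gcm_id),
      function(d) as.list(setNames(d$trend_per_decade, d$scenario))),
    warming_per_decade = as.list(climate$config$warming_per_decade),
    gcm_bias_sd = climate$config$gcm_bias_sd
  )
  yaml::write_yaml(truth, path)
  invisible(path)
}
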