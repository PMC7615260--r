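#' Configuration for the synthetic world generator
#'
#' Collects every knob of the synthetic-data module: survey design sizes, the
#' generating temperature effect and mediated fractions, outcome prevalence,
#' the pseudo-GCM ensemble layout, and the toy geography. Defaults encode the
#' study conditions the pipeline is meant to emulate: a generating odds ratio
#' of 1.138 per +1 degC of annual mean temperature, overall anemia prevalence
#' 63.76%, 11.40% of the temperature effect routed through child malnutrition
#' and 9.74% through malaria infection, a 20-member pseudo-GCM ensemble under
#' three emission scenarios whose linear warming ramps are calibrated so the
#' ensemble-mean 2090s warming relative to the 1985-2014 baseline is 4.0, 2.2
#' and 1.1 degC for the high, moderate and low scenario respectively.
#'
#' @param seed integer seed; the same config yields byte-identical outputs.
#' @param n_countries,clusters_per_country,children_per_cluster survey design
#'   sizes. Countries are laid out as adjacent rectangles on a toy grid.
#' @param beta_temp generating total log-odds of anemia per +1 degC annual
#'   mean temperature.
#' @param baseline_prevalence target marginal anemia prevalence, in (0, 1).
#' @param mediation_frac_malnutrition,mediation_frac_malaria fractions of
#'   `beta_temp` routed through each mediator (difference-of-coefficients
#'   sense); must sum to < 1.
#' @param n_gcms number of pseudo-GCM ensemble members.
#' @param scenarios character vector of scenario labels.
#' @param warming_per_decade named numeric vector (degC per decade) per
#'   scenario; the default is calibrated from the 2090s ensemble-mean warming
#'   targets above under the linear ramp starting in 2015.
#' @param gcm_bias_sd standard deviation (degC) of the per-GCM, per-calendar-
#'   month additive biases injected into pseudo-GCM series.
#' @param gcm_trend_spread relative spread of per-GCM warming-trend
#'   multipliers (mean 1), giving the ensemble its ΔT dispersion.
#' @param grid_resolution reference-grid cell size in degrees.
#' @param years integer length-2: calendar span of all daily series
#'   (reference and pseudo-GCMs share it).
#' @param survey_years integer length-2: calendar span of survey interviews.
#' @param cities_per_country number of rectangular "city" (admin-2) polygons
#'   each country is split into.
#' @param country_temp_range range (degC) of country-mean annual temperature
#'   across the toy domain.
#' @param seasonal_amplitude,sd_interannual,sd_daily seasonal half-range and
#'   interannual / day-to-day noise SDs (degC) of the reference series.
#' @param sd_city SD of the city-level random intercept on the log-odds scale.
#' @param sd_country_prev SD of country offsets (log-odds) around
#'   `baseline_prevalence`.
#' @param malnutrition_prevalence,malaria_prevalence mediator prevalences at
#'   the domain-mean temperature.
#' @param severity_temp_shift per-degC shift of the conditional severity
#'   distribution toward severe anemia (cumulative log-odds).
#' @param baseline_window integer length-2, the climatological baseline used
#'   for bias correction and ΔT (inclusive years).
#'
#' @return A `synth_config` list, validated.
#' @export
synth_config <- function(seed = 1L,
                         n_countries = 4L,
                         clusters_per_country = 30L,
                         children_per_cluster = 25L,
                         beta_temp = log(1.138),
                         baseline_prevalence = 0.6376,
                         mediation_frac_malnutrition = 0.114,
                         mediation_frac_malaria = 0.0974,
                         n_gcms = 20L,
                         scenarios = c("ssp126", "ssp245", "ssp585"),
                         warming_per_decade = NULL,
                         gcm_bias_sd = 1.0,
                         gcm_trend_spread = 0.08,
                         grid_resolution = 0.5,
                         years = c(1985L, 2099L),
                         survey_years = c(2012L, 2016L),
                         cities_per_country = 4L,
                         country_temp_range = c(17, 29),
                         seasonal_amplitude = 3,
                         sd_interannual = 0.5,
                         sd_daily = 1.5,
                         sd_city = 0.3,
                         sd_country_prev = 0.25,
                         malnutrition_prevalence = 0.22,
                         malaria_prevalence = 0.25,
                         severity_temp_shift = 0.05,
                         baseline_window = c(1985L, 2014L)) {
  if (is.null(warming_per_decade)) {
    # Linear ramp from 2015: decade-mean 2090s warming = trend/10 * mean(2090:2099 - 2015).
    ramp_2090s <- mean(2090:2099 - 2015) / 10
    targets <- c(ssp126 = 1.1, ssp245 = 2.2, ssp585 = 4.0)
    warming_per_decade <- (targets / ramp_2090s)[scenarios]
    if (anyNA(warming_per_decade)) {
      stop("no default warming_per_decade for scenarios outside ",
           "ssp126/ssp245/ssp585; supply `warming_per_decade`.", call. = FALSE)
    }
    names(warming_per_decade) <- scenarios
  }
  cfg <- list(
    seed = as.integer(seed), n_countries = as.integer(n_countries),
    clusters_per_country = as.integer(clusters_per_country),
    children_per_cluster = as.integer(children_per_cluster),
    beta_temp = beta_temp, baseline_prevalence = baseline_prevalence,
    mediation_frac_malnutrition = mediation_frac_malnutrition,
    mediation_frac_malaria = mediation_frac_malaria,
    n_gcms = as.integer(n_gcms), scenarios = scenarios,
    warming_per_decade = warming_per_decade, gcm_bias_sd = gcm_bias_sd,
    gcm_trend_spread = gcm_trend_spread, grid_resolution = grid_resolution,
    years = as.integer(years), survey_years = as.integer(survey_years),
    cities_per_country = as.integer(cities_per_country),
    country_temp_range = country_temp_range,
    seasonal_amplitude = seasonal_amplitude,
    sd_interannual = sd_interannual, sd_daily = sd_daily, sd_city = sd_city,
    sd_country_prev = sd_country_prev,
    malnutrition_prevalence = malnutrition_prevalence,
    malaria_prevalence = malaria_prevalence,
    severity_temp_shift = severity_temp_shift,
    baseline_window = as.integer(baseline_window)
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  stopifnot(length(cfg$years) == 2L, length(cfg$survey_years) == 2L,
            length(cfg$baseline_window) == 2L)
  if (cfg$baseline_prevalence <= 0 || cfg$baseline_prevalence >= 1) {
    stop("`baseline_prevalence` must lie strictly inside (0, 1).", call. = FALSE)
  }
  fr <- c(cfg$mediation_frac_malnutrition, cfg$mediation_frac_malaria)
  if (any(fr < 0) || sum(fr) >= 1) {
    stop("mediation fractions must be in [0, 1) and sum to < 1.", call. = FALSE)
  }
  if (cfg$n_gcms < 1L) stop("`n_gcms` must be at least 1.", call. = FALSE)
  if (!all(cfg$scenarios %in% names(cfg$warming_per_decade))) {
    stop("`warming_per_decade` must be named with every scenario label.",
         call. = FALSE)
  }
  if (cfg$survey_years[1] - cfg$years[1] < 11L) {
    stop("`years` must start at least 11 years before `survey_years` so annual ",
         "and decadal exposure windows have full history.", call. = FALSE)
  }
  if (cfg$n_countries < 1L || cfg$clusters_per_country < 1L ||
      cfg$children_per_cluster < 1L) {
    stop("survey design sizes must be positive.", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat(sprintf("  %d countries x %d clusters x %d children (seed %d)\n",
              x$n_countries, x$clusters_per_country, x$children_per_cluster,
              x$seed))
  cat(sprintf("  OR/degC %.3f, prevalence %.4f, mediated %.1f%% + %.1f%%\n",
              exp(x$beta_temp), x$baseline_prevalence,
              100 * x$mediation_frac_malnutrition,
              100 * x$mediation_frac_malaria))
  cat(sprintf("  %d GCMs, scenarios %s, years %d-%d\n", x$n_gcms,
              paste(x$scenarios, collapse = "/"), x$years[1], x$years[2]))
  invisible(x)
}

# Country rectangles of the toy geography: adjacent lon bands, fixed lat band.
country_layout <- function(cfg, width = 3, height = 3, lat0 = -8, lon0 = 10) {
  j <- seq_len(cfg$n_countries)
  regions <- c("Eastern", "Central", "Western", "Southern")
  tibble::tibble(
    country_code = sprintf("C%02d", j),
    region = regions[(j - 1L) %% length(regions) + 1L],
    lon_min = lon0 + (j - 1) * width, lon_max = lon0 + j * width,
    lat_min = lat0, lat_max = lat0 + height
  )
}
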