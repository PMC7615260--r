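#' Excess anemia cases attributable to warming
#'
#' The attribution kernel: for a city,
#' \deqn{Excess = Pop_c \times Rate_c \times ERC_c \times \Delta T}
#' with `pop` the under-5 population, `rate` the baseline anemia prevalence,
#' `erc` the excess risk coefficient (risk ratio minus one, a fraction per
#' +1 degC) and `delta_t` the annual warming relative to baseline. Negative
#' values (cooling) are retained as negative excess.
#'
#' @param pop under-5 population (persons), non-negative.
#' @param rate baseline prevalence in `[0, 1]`.
#' @param erc excess risk coefficient per degC, greater than -1.
#' @param delta_t warming in degC.
#' @return Excess annual cases (vectorized).
#' @export
excess_cases <- function(pop, rate, erc, delta_t) {
  if (any(pop < 0, na.rm = TRUE)) stop("`pop` must be non-negative.", call. = FALSE)
  if (any(rate < 0 | rate > 1, na.rm = TRUE)) {
    stop("`rate` must lie in [0, 1].", call. = FALSE)
  }
  if (any(erc <= -1, na.rm = TRUE)) stop("`erc` must exceed -1.", call. = FALSE)
  pop * rate * erc * delta_t
}

decade_label <- function(year) paste0(year %/% 10L * 10L, "s")

# Long table of annual city excess for given per-country ERCs.
city_annual_excess <- function(fits, deltas, pops) {
  missing_fit <- setdiff(unique(pops$country_code), fits$country_code)
  if (length(missing_fit)) {
    stop("no association fit for country: ",
         paste(missing_fit, collapse = ", "), call. = FALSE)
  }
  d <- dplyr::inner_join(deltas,
                         pops[, c("city_id", "country_code", "region",
                                  "under5_pop")],
                         by = "city_id")
  d <- dplyr::inner_join(d, fits[, c("country_code", "rate", "erc")],
                         by = "country_code")
  d$excess <- excess_cases(d$under5_pop, d$rate, d$erc, d$delta_t)
  d$decade <- decade_label(d$year)
  d
}

# Aggregate annual city excess to scope x decade x scenario x gcm means.
aggregate_excess <- function(d, pops, scopes) {
  denom <- list(
    city = setNames(pops$under5_pop, pops$city_id),
    country = tapply(pops$under5_pop, pops$country_code, sum),
    region = tapply(pops$under5_pop, pops$region, sum),
    total = c(total = sum(pops$under5_pop))
  )
  purrr::map_dfr(scopes, function(sc) {
    key <- switch(sc, city = d$city_id, country = d$country_code,
                  region = d$region, total = rep("total", nrow(d)))
    agg <- dplyr::summarise(
      dplyr::group_by(tibble::tibble(scope = key, decade = d$decade,
                                     scenario = d$scenario, gcm_id = d$gcm_id,
                                     year = d$year, excess = d$excess),
                      .data$scope, .data$decade, .data$scenario,
                      .data$gcm_id, .data$year),
      excess = sum(.data$excess), .groups = "drop")
    agg <- dplyr::summarise(
      dplyr::group_by(agg, .data$scope, .data$decade, .data$scenario,
                      .data$gcm_id),
      excess = mean(.data$excess), .groups = "drop")   # decade = mean of years
    agg$scope_level <- sc
    agg$denom_pop <- denom[[sc]][agg$scope]
    agg
  })
}

#' Attribute future anemia burden to warming
#'
#' Projects excess childhood anemia cases per 100,000 person-years by scope
#' (city, country, region, total), decade and scenario. For every
#' city-year-GCM-scenario the excess is `pop * rate_c * erc_c * delta_t`
#' with the country's prevalence and excess risk coefficient and the city's
#' under-5 population; a decade's value is the mean of its annual values;
#' the point estimate is the mean across ensemble members at the central
#' coefficients; normalization divides by the scope's baseline under-5
#' population (held fixed — the no-population-change assumption of the main
#' analysis; pass decade-specific `pops_future` for the future-population
#' variant, which keeps the baseline denominator). Empirical 95% CIs come
#' from Monte Carlo coefficient draws pooled across ensemble members
#' ([monte_carlo_eci()]).
#'
#' @param fits per-country association table from
#'   [fit_country_associations()] (`country_code`, `beta`, `se`, `rate`,
#'   `erc`).
#' @param deltas ΔT table from [delta_t()].
#' @param pops baseline city population table from
#'   [build_city_population()] (one row per city).
#' @param pops_future optional city population table with `decade` and
#'   `scenario` columns for the future-population variant.
#' @param scopes aggregation levels to report.
#' @param n_draws Monte Carlo coefficient draws for the eCIs (0 skips them).
#' @param seed seed for the coefficient draws.
#' @return A `burden_result` tibble: `scope_level`, `scope`, `decade`,
#'   `scenario`, `excess_cases`, `burden_per_100k`, `eci_low`, `eci_high`
#'   (per-100k scale), `n_gcms`, `n_draws`.
#' @export
attribute_burden <- function(fits, deltas, pops, pops_future = NULL,
                             scopes = c("city", "country", "region", "total"),
                             n_draws = 1000, seed = 1L) {
  zero <- pops$under5_pop == 0
  if (any(zero)) {
    warning("excluding zero-population cities from per-100k normalization: ",
            paste(pops$city_id[zero], collapse = ", "), call. = FALSE)
  }
  use_pops <- pops
  d <- city_annual_excess(fits, deltas, use_pops)
  if (!is.null(pops_future)) {
    # future-population variant: numerator population varies by decade and
    # scenario, the per-100k denominator stays at baseline
    pf <- pops_future
    pf$decade_lab <- decade_label(pf$decade)
    d$decade_lab <- d$decade
    m <- match(paste(d$city_id, d$scenario, d$decade_lab),
               paste(pf$city_id, pf$scenario, pf$decade_lab))
    scale <- pf$under5_pop[m] / d$under5_pop
    scale[is.na(scale)] <- 1
    d$excess <- d$excess * scale
    d$decade_lab <- NULL
  }
  agg <- aggregate_excess(d, pops, scopes)
  agg$burden_per_100k <- 1e5 * agg$excess / agg$denom_pop
  point <- dplyr::summarise(
    dplyr::group_by(agg, .data$scope_level, .data$scope, .data$decade,
                    .data$scenario),
    excess_cases = mean(.data$excess),
    burden_per_100k = mean(.data$burden_per_100k),
    n_gcms = dplyr::n(), .groups = "drop")
  if (n_draws > 0) {
    eci <- monte_carlo_eci(fits, deltas, pops, n_draws = n_draws, seed = seed,
                           scopes = scopes, pops_future = pops_future)
    point <- dplyr::left_join(
      point, eci, by = c("scope_level", "scope", "decade", "scenario"))
  } else {
    point$eci_low <- NA_real_
    point$eci_high <- NA_real_
  }
  point$n_draws <- n_draws
  class(point) <- c("burden_result", class(point))
  point
}

#' Monte Carlo empirical confidence intervals for the burden
#'
#' Propagates coefficient uncertainty and ensemble spread: for each draw the
#' country log-odds coefficients are sampled from
#' `Normal(beta_hat, se)` independently per country, the excess risk
#' coefficient is rebuilt through the OR-to-RR conversion at the country
#' prevalence, and the burden is recomputed for every ensemble member; the
#' 2.5th and 97.5th percentiles of the pooled draws-by-members distribution
#' give the empirical CI. Burden is linear in the per-country ERC, so draws
#' reuse precomputed per-country aggregates.
#'
#' @inheritParams attribute_burden
#' @param n_draws number of coefficient draws (the reference analysis uses
#'   1,000).
#' @return A tibble: `scope_level`, `scope`, `decade`, `scenario`,
#'   `eci_low`, `eci_high` (per-100k scale).
#' @export
monte_carlo_eci <- function(fits, deltas, pops, n_draws = 1000, seed = 1L,
                            scopes = c("city", "country", "region", "total"),
                            pops_future = NULL) {
  if (any(fits$se < 0)) stop("negative standard errors in `fits`.", call. = FALSE)
  if (n_draws < 1) stop("`n_draws` must be at least 1.", call. = FALSE)
  d <- city_annual_excess(fits, deltas, pops)
  if (!is.null(pops_future)) {
    pf <- pops_future
    pf$decade_lab <- decade_label(pf$decade)
    m <- match(paste(d$city_id, d$scenario, d$decade),
               paste(pf$city_id, pf$scenario, pf$decade_lab))
    scale <- pf$under5_pop[m] / d$under5_pop
    scale[is.na(scale)] <- 1
    d$kernel <- d$under5_pop * scale * d$rate * d$delta_t
  } else {
    d$kernel <- d$under5_pop * d$rate * d$delta_t  # excess = kernel * erc_c
  }
  denom <- list(
    city = setNames(pops$under5_pop, pops$city_id),
    country = tapply(pops$under5_pop, pops$country_code, sum),
    region = tapply(pops$under5_pop, pops$region, sum),
    total = c(total = sum(pops$under5_pop))
  )
  set.seed(seed)
  draws_beta <- matrix(rnorm(nrow(fits) * n_draws, mean = fits$beta,
                             sd = fits$se),
                       nrow = nrow(fits))
  erc_draws <- or_to_rr(exp(draws_beta), fits$rate) - 1  # country x draw
  rownames(erc_draws) <- fits$country_code
  purrr::map_dfr(scopes, function(sc) {
    key <- switch(sc, city = d$city_id, country = d$country_code,
                  region = d$region, total = rep("total", nrow(d)))
    # per (scope, decade, scenario, gcm, country): decade-mean kernel sum
    k <- dplyr::summarise(
      dplyr::group_by(tibble::tibble(scope = key, decade = d$decade,
                                     scenario = d$scenario, gcm_id = d$gcm_id,
                                     country = d$country_code, year = d$year,
                                     kernel = d$kernel),
                      .data$scope, .data$decade, .data$scenario, .data$gcm_id,
                      .data$country),
      kernel = sum(.data$kernel) / length(unique(.data$year)),
      .groups = "drop")
    cells <- dplyr::distinct(k[, c("scope", "decade", "scenario")])
    purrr::map_dfr(seq_len(nrow(cells)), function(i) {
      ki <- k[k$scope == cells$scope[i] & k$decade == cells$decade[i] &
                k$scenario == cells$scenario[i], ]
      # gcm x draw burden: sum over countries of kernel * erc draw
      km <- tapply(ki$kernel, list(ki$gcm_id, ki$country), sum)
      km[is.na(km)] <- 0
      vals <- km %*% erc_draws[colnames(km), , drop = FALSE]
      q <- quantile(1e5 * vals / denom[[sc]][[cells$scope[i]]],
                    c(0.025, 0.975), names = FALSE)
      tibble::tibble(scope_level = sc, scope = cells$scope[i],
                     decade = cells$decade[i], scenario = cells$scenario[i],
                     eci_low = q[1], eci_high = q[2])
    })
  })
}

#' @export
print.burden_result <- function(x, ...) {
  cat(sprintf("<burden_result: %d rows, %d GCMs, %d coefficient draws>\n",
              nrow(x), max(x$n_gcms), max(x$n_draws)))
  NextMethod()
}

#' Write a burden table and run manifest
#'
#' @param burden a `burden_result`.
#' @param dir output directory; writes `burden.csv` and `manifest.json`.
#' @param manifest named list of run metadata merged into the manifest.
#' @return The directory, invisibly.
#' @export
write_burden_csv <- function(burden, dir, manifest = list()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(as.data.frame(burden), file.path(dir, "burden.csv"),
            row.names = FALSE)
  manifest <- c(list(written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                     rows = nrow(burden)), manifest)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
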