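#' Bilinear regrid of a gridded field
#'
#' Interpolates a field to a new regular grid over the same bounding box
#' using bilinear interpolation at the target cell centers (values clamped
#' to the outermost source cell centers). A plane `a + b*lat + c*lon` is
#' reproduced exactly at any target point.
#'
#' @param field a [grid_field()].
#' @param target_resolution target cell size in degrees.
#' @return A [grid_field()] at the target resolution.
#' @export
regrid_bilinear <- function(field, target_resolution) {
  bbox <- grid_bbox(field)
  lat_t <- seq(bbox["lat_min"] + target_resolution / 2,
               bbox["lat_max"] - target_resolution / 2, by = target_resolution)
  lon_t <- seq(bbox["lon_min"] + target_resolution / 2,
               bbox["lon_max"] - target_resolution / 2, by = target_resolution)
  if (length(lat_t) < 1L || length(lon_t) < 1L) {
    stop("target resolution too coarse for the source bounding box.",
         call. = FALSE)
  }
  nt <- length(field$time)
  out <- array(NA_real_, dim = c(length(lat_t), length(lon_t), nt))
  for (i in seq_along(lat_t)) {
    for (j in seq_along(lon_t)) {
      out[i, j, ] <- bilinear_point(field, lat_t[i], lon_t[j])
    }
  }
  grid_field(lat_t, lon_t, field$time, out, variable = field$variable)
}

#' Additive-scaling (delta) bias correction against a reference series
#'
#' Shifts a climate-model temperature field so that its calibration-period
#' climatology matches the reference's:
#' \deqn{corrected(t) = gcm(t) - \bar{gcm}_{m(t)} + \bar{ref}_{m(t)}}
#' where the climatological means are taken per calendar month (the standard
#' dialect of additive scaling; `granularity = "annual"` uses a single
#' offset) over the calibration window, per grid cell. Offsets are purely
#' additive, so variance and future trends are untouched and the correction
#' is idempotent.
#'
#' @param gcm_field,reference_field temperature [grid_field()]s on the same
#'   grid; the reference must cover the calibration window.
#' @param calibration_window integer length-2, inclusive years (default the
#'   1985-2014 attribution baseline).
#' @param granularity `"month"` (12 offsets per cell) or `"annual"`.
#' @return The corrected [grid_field()], with the per-cell offsets attached
#'   as attribute `"offsets"` for diagnostics.
#' @export
bias_correct <- function(gcm_field, reference_field,
                         calibration_window = c(1985, 2014),
                         granularity = c("month", "annual")) {
  granularity <- match.arg(granularity)
  yr_g <- as.integer(format(gcm_field$time, "%Y"))
  yr_r <- as.integer(format(reference_field$time, "%Y"))
  overlap <- intersect(
    intersect(unique(yr_g), unique(yr_r)),
    calibration_window[1]:calibration_window[2])
  if (length(overlap) < 5L) {
    stop("fewer than 5 years of calibration overlap between the series.",
         call. = FALSE)
  }
  if (length(overlap) < 20L) {
    warning("calibration overlap is only ", length(overlap),
            " years; offsets will be noisy.", call. = FALSE)
  }
  if (!identical(dim(gcm_field$values)[1:2], dim(reference_field$values)[1:2])) {
    stop("GCM and reference fields must share a grid; regrid first.",
         call. = FALSE)
  }
  ncell <- prod(dim(gcm_field$values)[1:2])
  g <- matrix(gcm_field$values, nrow = ncell)
  r <- matrix(reference_field$values, nrow = ncell)
  mon_g <- if (granularity == "month") as.integer(format(gcm_field$time, "%m"))
           else rep(1L, length(gcm_field$time))
  mon_r <- if (granularity == "month") as.integer(format(reference_field$time, "%m"))
           else rep(1L, length(reference_field$time))
  calib_g <- yr_g %in% overlap
  calib_r <- yr_r %in% overlap
  months <- sort(unique(mon_g))
  offsets <- matrix(NA_real_, nrow = ncell, ncol = length(months))
  corrected <- g
  for (m in seq_along(months)) {
    sel_g <- calib_g & mon_g == months[m]
    sel_r <- calib_r & mon_r == months[m]
    off <- rowMeans(r[, sel_r, drop = FALSE]) -
      rowMeans(g[, sel_g, drop = FALSE])
    offsets[, m] <- off
    corrected[, mon_g == months[m]] <-
      corrected[, mon_g == months[m], drop = FALSE] + off
  }
  out <- grid_field(gcm_field$lat, gcm_field$lon, gcm_field$time,
                    array(corrected, dim = dim(gcm_field$values)),
                    variable = "temperature")
  attr(out, "offsets") <- offsets
  out
}

# Indices of grid cells whose centers fall inside a rectangle; nearest-cell
# fallback (flagged) when no center is covered.
cells_in_rect <- function(field, b) {
  ii <- which(field$lat >= b$lat_min & field$lat <= b$lat_max)
  jj <- which(field$lon >= b$lon_min & field$lon <= b$lon_max)
  if (length(ii) && length(jj)) {
    list(cells = as.matrix(expand.grid(i = ii, j = jj)), fallback = FALSE)
  } else {
    ij <- nearest_cell(field, (b$lat_min + b$lat_max) / 2,
                       (b$lon_min + b$lon_max) / 2)
    list(cells = matrix(ij, nrow = 1,
                        dimnames = list(NULL, c("i", "j"))), fallback = TRUE)
  }
}

#' Aggregate a gridded field to city-level series
#'
#' Unweighted mean over the grid cells whose centers fall inside each city
#' polygon (rectangles in the synthetic world). Cities covering no cell
#' center fall back to the cell nearest the polygon centroid, with a
#' message.
#'
#' @param field a [grid_field()].
#' @param boundaries boundary tibble from [generate_boundaries()] (or
#'   [read_boundaries_geojson()]).
#' @return A tibble in long form: `city_id`, `time`, `value`.
#' @export
city_aggregate <- function(field, boundaries) {
  m <- city_series_matrix(field, boundaries)
  tibble::tibble(city_id = rep(boundaries$city_id, each = length(m$time)),
                 time = rep(m$time, times = nrow(boundaries)),
                 value = as.vector(m$values))
}

city_series_matrix <- function(field, boundaries) {
  if (any(boundaries$lon_max <= boundaries$lon_min |
            boundaries$lat_max <= boundaries$lat_min)) {
    bad <- boundaries$city_id[boundaries$lon_max <= boundaries$lon_min |
                                boundaries$lat_max <= boundaries$lat_min]
    stop("invalid (empty) polygon for city: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ncell <- prod(dim(field$values)[1:2])
  flat <- matrix(field$values, nrow = ncell)
  nlat <- length(field$lat)
  vals <- vapply(seq_len(nrow(boundaries)), function(cty) {
    hit <- cells_in_rect(field, boundaries[cty, ])
    if (hit$fallback) {
      message("city ", boundaries$city_id[cty],
              " covers no cell center; using nearest cell.")
    }
    lin <- (hit$cells[, "j"] - 1L) * nlat + hit$cells[, "i"]
    colMeans(flat[lin, , drop = FALSE])
  }, numeric(length(field$time)))
  list(time = field$time,
       values = matrix(vals, ncol = nrow(boundaries),
                       dimnames = list(NULL, boundaries$city_id)))
}

#' Build the bias-corrected city-level GCM ensemble
#'
#' Runs the projection preprocessing chain for every ensemble member and
#' scenario: realize the raw pseudo-GCM field, bilinearly regrid it (and the
#' reference) to the target resolution, bias-correct against the regridded
#' reference by additive scaling over the baseline window, aggregate to city
#' level, and reduce to annual means. Only the annual city series and
#' baseline means are retained.
#'
#' @param climate a `synth_climate` from [generate_climate()].
#' @param boundaries city boundary tibble.
#' @param target_resolution regrid target in degrees (default 1.0).
#' @param baseline_window inclusive years of the climatological baseline.
#' @param scenarios,gcm_ids subsets to process (defaults: all in `climate`).
#' @return A `gcm_ensemble` object: `annual` (tibble: gcm_id, scenario,
#'   city_id, year, annual_mean), `baseline` (tibble: gcm_id, scenario,
#'   city_id, baseline_mean) and metadata.
#' @export
build_gcm_ensemble <- function(climate, boundaries, target_resolution = 1.0,
                               baseline_window = NULL,
                               scenarios = NULL, gcm_ids = NULL) {
  stopifnot(inherits(climate, "synth_climate"))
  baseline_window <- baseline_window %||% climate$config$baseline_window
  scenarios <- scenarios %||% climate$config$scenarios
  gcm_ids <- gcm_ids %||% unique(climate$gcm_bias$gcm_id)
  ref1 <- regrid_bilinear(climate$ref_temperature, target_resolution)
  yr <- as.integer(format(ref1$time, "%Y"))
  combos <- tidyr::expand_grid(gcm_id = gcm_ids, scenario = scenarios)
  res <- purrr::map(seq_len(nrow(combos)), function(i) {
    raw <- realize_gcm(climate, combos$gcm_id[i], combos$scenario[i])
    g1 <- regrid_bilinear(raw, target_resolution)
    corr <- bias_correct(g1, ref1, calibration_window = baseline_window)
    cm <- city_series_matrix(corr, boundaries)
    ann <- rowsum(cm$values, yr) / as.vector(table(yr))
    base <- colMeans(ann[rownames(ann) %in%
                           as.character(baseline_window[1]:baseline_window[2]),
                         , drop = FALSE])
    list(
      annual = tibble::tibble(
        gcm_id = combos$gcm_id[i], scenario = combos$scenario[i],
        city_id = rep(colnames(ann), each = nrow(ann)),
        year = rep(as.integer(rownames(ann)), times = ncol(ann)),
        annual_mean = as.vector(ann)),
      baseline = tibble::tibble(
        gcm_id = combos$gcm_id[i], scenario = combos$scenario[i],
        city_id = names(base), baseline_mean = unname(base))
    )
  })
  structure(list(
    annual = dplyr::bind_rows(purrr::map(res, "annual")),
    baseline = dplyr::bind_rows(purrr::map(res, "baseline")),
    baseline_window = baseline_window,
    target_resolution = target_resolution,
    boundaries = boundaries),
    class = "gcm_ensemble")
}

#' @export
print.gcm_ensemble <- function(x, ...) {
  cat(sprintf("<gcm_ensemble: %d GCMs x %d scenarios x %d cities, baseline %d-%d>\n",
              length(unique(x$annual$gcm_id)),
              length(unique(x$annual$scenario)),
              length(unique(x$annual$city_id)),
              x$baseline_window[1], x$baseline_window[2]))
  invisible(x)
}

#' Warming relative to the climatological baseline
#'
#' ΔT per city-year-GCM-scenario: the bias-corrected annual mean minus that
#' member's city baseline mean over the baseline window.
#'
#' @param ensemble a `gcm_ensemble` from [build_gcm_ensemble()].
#' @param years optional integer vector restricting the years returned.
#' @return A tibble: `gcm_id`, `scenario`, `city_id`, `year`, `delta_t`.
#' @export
delta_t <- function(ensemble, years = NULL) {
  stopifnot(inherits(ensemble, "gcm_ensemble"))
  d <- dplyr::left_join(ensemble$annual, ensemble$baseline,
                        by = c("gcm_id", "scenario", "city_id"))
  if (!is.null(years)) d <- d[d$year %in% years, ]
  tibble::tibble(gcm_id = d$gcm_id, scenario = d$scenario,
                 city_id = d$city_id, year = d$year,
                 delta_t = d$annual_mean - d$baseline_mean)
}

#' City-level under-5 population table
#'
#' Sums the population grid cells whose centers fall inside each city
#' polygon and applies the country under-5 proportion of the matching
#' decade and scenario — the construction used for the projection
#' denominator and the future-population variant.
#'
#' @param population a `synth_population` from [generate_population()].
#' @param boundaries city boundary tibble.
#' @param decade decade start year (`2020` baseline).
#' @param scenario scenario label or `NULL` for the baseline grid.
#' @return A tibble: `city_id`, `country_code`, `region`, `decade`,
#'   `scenario`, `total_pop`, `under5_proportion`, `under5_pop`.
#' @export
build_city_population <- function(population, boundaries, decade = 2020,
                                  scenario = NULL) {
  stopifnot(inherits(population, "synth_population"))
  if (is.null(scenario)) {
    field <- population$total_baseline; dec <- 2020
    scen <- population$config$scenarios[1]
  } else {
    field <- population$total_future[[scenario]]; dec <- decade; scen <- scenario
  }
  k <- match(dec, field$time)
  if (is.na(k)) stop("decade ", dec, " not present in the population grids.",
                     call. = FALSE)
  slice <- grid_field(field$lat, field$lon, dec,
                      field$values[, , k, drop = FALSE],
                      variable = "population")
  pr <- population$proportions
  pr <- pr[pr$scenario == scen & pr$decade == dec, ]
  out <- purrr::map_dfr(seq_len(nrow(boundaries)), function(cty) {
    hit <- cells_in_rect(slice, boundaries[cty, ])
    lin <- (hit$cells[, "j"] - 1L) * length(slice$lat) + hit$cells[, "i"]
    total <- sum(matrix(slice$values, nrow = prod(dim(slice$values)[1:2]))[lin, 1])
    prop <- pr$under5_proportion[pr$country_code == boundaries$country_code[cty]]
    if (total == 0) warning("city ", boundaries$city_id[cty],
                            " has zero population.", call. = FALSE)
    tibble::tibble(city_id = boundaries$city_id[cty],
                   country_code = boundaries$country_code[cty],
                   region = boundaries$region[cty],
                   decade = dec, scenario = if (is.null(scenario)) NA_character_ else scen,
                   total_pop = total, under5_proportion = prop,
                   under5_pop = total * prop)
  })
  out
}
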