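#' Generate synthetic city boundaries
#'
#' Splits each country rectangle of the toy geography into a grid of
#' rectangular "city" polygons (the stand-in for admin-level-2 boundaries).
#'
#' @param config a [synth_config()].
#' @return A tibble with one row per city: `city_id`, `country_code`,
#'   `region`, and rectangle bounds `lon_min/lon_max/lat_min/lat_max`.
#' @export
generate_boundaries <- function(config) {
  validate_synth_config(config)
  layout <- country_layout(config)
  k <- config$cities_per_country
  ncol_c <- ceiling(sqrt(k)); nrow_c <- ceiling(k / ncol_c)
  purrr::map_dfr(seq_len(nrow(layout)), function(i) {
    cc <- layout[i, ]
    idx <- seq_len(k) - 1L
    cx <- idx %% ncol_c; cy <- idx %/% ncol_c
    w <- (cc$lon_max - cc$lon_min) / ncol_c
    h <- (cc$lat_max - cc$lat_min) / nrow_c
    tibble::tibble(
      city_id = sprintf("%s_city%02d", cc$country_code, idx + 1L),
      country_code = cc$country_code, region = cc$region,
      lon_min = cc$lon_min + cx * w, lon_max = cc$lon_min + (cx + 1) * w,
      lat_min = cc$lat_min + cy * h, lat_max = cc$lat_min + (cy + 1) * h
    )
  })
}

#' Write / read city boundaries as GeoJSON
#'
#' Serializes the rectangular city polygons as a GeoJSON FeatureCollection
#' (one Polygon feature per city with `city_id`, `country_code` and `region`
#' properties) and reads such files back to the boundary tibble.
#'
#' @param boundaries a boundary tibble from [generate_boundaries()].
#' @param path file path.
#' @return `write_boundaries_geojson` returns `path` invisibly;
#'   `read_boundaries_geojson` returns a boundary tibble.
#' @export
write_boundaries_geojson <- function(boundaries, path) {
  features <- purrr::map(seq_len(nrow(boundaries)), function(i) {
    b <- boundaries[i, ]
    ring <- list(c(b$lon_min, b$lat_min), c(b$lon_max, b$lat_min),
                 c(b$lon_max, b$lat_max), c(b$lon_min, b$lat_max),
                 c(b$lon_min, b$lat_min))
    list(type = "Feature",
         properties = list(city_id = b$city_id, country_code = b$country_code,
                           region = b$region),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_boundaries_geojson
#' @export
read_boundaries_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  purrr::map_dfr(gj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    lons <- vapply(ring, function(p) p[[1]], numeric(1))
    lats <- vapply(ring, function(p) p[[2]], numeric(1))
    tibble::tibble(city_id = f$properties$city_id,
                   country_code = f$properties$country_code,
                   region = f$properties$region,
                   lon_min = min(lons), lon_max = max(lons),
                   lat_min = min(lats), lat_max = max(lats))
  })
}

#' Generate synthetic population grids and under-5 proportions
#'
#' Builds a baseline total-population grid (epoch 2020) over the toy
#' geography, projected total-population grids per decade and scenario
#' (baseline grid scaled by a stylized scenario growth factor), and a
#' country-by-decade-by-scenario table of under-5 population proportions.
#' Under-5 grids are constructed, exactly as the attribution pipeline
#' assumes, as the total grid times the country proportion of the matching
#' decade and scenario.
#'
#' @param config a [synth_config()].
#' @param decades integer vector of decade start years for the projections.
#' @return A `synth_population` list: `total_baseline` ([grid_field()],
#'   epoch 2020), `total_future` (tibble-indexed list of grid fields with a
#'   decade time axis per scenario), `proportions` (tibble: country_code,
#'   scenario, decade, under5_proportion), `config`.
#' @export
generate_population <- function(config, decades = seq(2020L, 2090L, by = 10L)) {
  validate_synth_config(config)
  set.seed(config$seed + 23L)
  layout <- country_layout(config)
  res <- config$grid_resolution
  lon <- seq(min(layout$lon_min) + res / 2, max(layout$lon_max) - res / 2, by = res)
  lat <- seq(min(layout$lat_min) + res / 2, max(layout$lat_max) - res / 2, by = res)
  nlat <- length(lat); nlon <- length(lon)
  base <- matrix(exp(rnorm(nlat * nlon, mean = log(2e4), sd = 0.8)),
                 nrow = nlat)
  total_baseline <- grid_field(lat, lon, 2020, base, variable = "population")

  growth <- c(ssp126 = 1.08, ssp245 = 1.12, ssp585 = 1.16)  # per decade
  growth <- growth[config$scenarios]
  growth[is.na(growth)] <- 1.10
  names(growth) <- config$scenarios
  total_future <- lapply(config$scenarios, function(sc) {
    vals <- vapply(decades, function(d) base * growth[[sc]]^((d - 2020) / 10),
                   base)
    grid_field(lat, lon, decades, array(vals, c(nlat, nlon, length(decades))),
               variable = "population")
  })
  names(total_future) <- config$scenarios

  # Under-5 share: ~15% at baseline, drifting down faster in low-fertility
  # scenarios, with a small country-level offset.
  decline <- c(ssp126 = 0.004, ssp245 = 0.003, ssp585 = 0.002)
  decline <- ifelse(is.na(decline[config$scenarios]), 0.003,
                    decline[config$scenarios])
  names(decline) <- config$scenarios
  offs <- rnorm(nrow(layout), sd = 0.01)
  proportions <- tidyr::expand_grid(country_code = layout$country_code,
                                    scenario = config$scenarios,
                                    decade = decades)
  proportions$under5_proportion <- pmin(pmax(
    0.15 + offs[match(proportions$country_code, layout$country_code)] -
      decline[proportions$scenario] * (proportions$decade - 2020) / 10,
    0.02), 0.35)

  structure(list(total_baseline = total_baseline, total_future = total_future,
                 proportions = proportions, layout = layout, config = config),
            class = "synth_population")
}

#' Under-5 population grid for one decade and scenario
#'
#' Multiplies a total-population grid by the country-specific under-5
#' proportion of the matching decade and scenario, assigning each grid cell
#' to the country rectangle containing its center.
#'
#' @param population a `synth_population` from [generate_population()].
#' @param decade decade start year; `2020` with `scenario = NULL` gives the
#'   baseline under-5 grid.
#' @param scenario scenario label, or `NULL` for the baseline grid (the
#'   baseline uses the first scenario's proportions at 2020, which coincide
#'   across scenarios by construction).
#' @return A population [grid_field()] with a single time slice.
#' @export
under5_grid <- function(population, decade = 2020, scenario = NULL) {
  stopifnot(inherits(population, "synth_population"))
  layout <- population$layout
  if (is.null(scenario)) {
    field <- population$total_baseline
    slice <- field$values[, , 1]
    scen <- population$config$scenarios[1]
    dec <- 2020
  } else {
    field <- population$total_future[[scenario]]
    k <- match(decade, field$time)
    if (is.na(k)) stop("decade ", decade, " not in the population grids.",
                       call. = FALSE)
    slice <- field$values[, , k]
    scen <- scenario
    dec <- decade
  }
  pr <- population$proportions
  cell_country <- layout$country_code[
    findInterval(field$lon, layout$lon_min, rightmost.closed = TRUE)]
  prop_by_country <- pr$under5_proportion[pr$scenario == scen & pr$decade == dec]
  names(prop_by_country) <- pr$country_code[pr$scenario == scen & pr$decade == dec]
  mult <- matrix(prop_by_country[cell_country], nrow = length(field$lat),
                 ncol = length(field$lon), byrow = TRUE)
  grid_field(field$lat, field$lon, dec, slice * mult, variable = "population")
}
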