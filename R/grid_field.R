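#' Gridded field container
#'
#' A regular latitude-longitude grid holding one variable, either as a daily
#' time series (temperature, precipitation) or a single epoch (population).
#' Values are stored as a dense array with dimensions `lat x lon x time`;
#' grid cells are identified by their centers and spaced `resolution` degrees
#' apart. All daily axes use a 365-day calendar (leap days dropped) so that
#' climate-model and reference series align without calendar bookkeeping.
#'
#' @param lat,lon numeric vectors of cell-center coordinates, equally spaced,
#'   strictly increasing.
#' @param time a `Date` vector (daily axis) or a numeric vector of epochs
#'   (e.g. decade start years) for time-invariant or decadal fields.
#' @param values numeric array `length(lat) x length(lon) x length(time)`.
#'   A matrix is accepted when there is a single time slice.
#' @param variable one of `"temperature"` (degC), `"precipitation"` (mm/day),
#'   `"population"` (persons).
#'
#' @return An object of class `grid_field`.
#' @export
grid_field <- function(lat, lon, time, values,
                       variable = c("temperature", "precipitation", "population")) {
  variable <- match.arg(variable)
  if (is.matrix(values)) values <- array(values, dim = c(dim(values), 1L))
  stopifnot(is.array(values), length(dim(values)) == 3L)
  if (!all(dim(values) == c(length(lat), length(lon), length(time)))) {
    stop("`values` must be a lat x lon x time array matching the coordinate axes.",
         call. = FALSE)
  }
  if (is.unsorted(lat, strictly = TRUE) || is.unsorted(lon, strictly = TRUE)) {
    stop("`lat` and `lon` must be strictly increasing cell-center coordinates.",
         call. = FALSE)
  }
  res_lat <- if (length(lat) > 1) diff(lat)[1] else NA_real_
  res_lon <- if (length(lon) > 1) diff(lon)[1] else res_lat
  if (is.na(res_lat)) res_lat <- res_lon
  if (variable == "temperature" && any(values < -90 | values > 60, na.rm = TRUE)) {
    stop("temperature values outside a physically plausible range.", call. = FALSE)
  }
  structure(
    list(lat = as.numeric(lat), lon = as.numeric(lon), time = time,
         values = values, variable = variable,
         resolution = c(lat = res_lat, lon = res_lon)),
    class = "grid_field"
  )
}

#' @export
print.grid_field <- function(x, ...) {
  cat(sprintf("<grid_field: %s, %d x %d cells, %d time steps, ~%.3g deg>\n",
              x$variable, length(x$lat), length(x$lon), length(x$time),
              mean(x$resolution, na.rm = TRUE)))
  cat(sprintf("  lat [%.3f, %.3f]  lon [%.3f, %.3f]\n",
              min(x$lat), max(x$lat), min(x$lon), max(x$lon)))
  invisible(x)
}

#' @export
as_tibble.grid_field <- function(x, ...) {
  grid <- expand.grid(lat = x$lat, lon = x$lon, time = x$time,
                      KEEP.OUT.ATTRS = FALSE)
  tibble::tibble(lat = grid$lat, lon = grid$lon, time = grid$time,
                 value = as.vector(x$values), variable = x$variable)
}

#' Bounding box of a grid (outer cell edges)
#' @param field a [grid_field()].
#' @return named numeric vector `lat_min, lat_max, lon_min, lon_max`.
#' @export
grid_bbox <- function(field) {
  hl <- field$resolution[["lat"]] / 2
  ho <- field$resolution[["lon"]] / 2
  c(lat_min = min(field$lat) - hl, lat_max = max(field$lat) + hl,
    lon_min = min(field$lon) - ho, lon_max = max(field$lon) + ho)
}

#' Write / read a gridded field as CF-style plain text
#'
#' Serializes a [grid_field()] to a long-format CSV with `lat, lon, time,
#' value` columns plus a one-line `#` header carrying the variable name, so
#' grids round-trip losslessly through version-controllable text files.
#'
#' @param field a [grid_field()].
#' @param path file path.
#' @return `write_grid_csv` returns `path` invisibly; `read_grid_csv` returns
#'   a [grid_field()].
#' @export
write_grid_csv <- function(field, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# grid_field variable=%s time_class=%s", field$variable,
                     if (inherits(field$time, "Date")) "Date" else "numeric"), con)
  df <- as.data.frame(as_tibble(field)[, c("lat", "lon", "time", "value")])
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  variable <- sub(".*variable=(\\S+).*", "\\1", hdr)
  time_class <- sub(".*time_class=(\\S+).*", "\\1", hdr)
  df <- read.csv(path, skip = 1L)
  if (time_class == "Date") df$time <- as.Date(df$time)
  lat <- sort(unique(df$lat)); lon <- sort(unique(df$lon))
  time <- sort(unique(df$time))
  df <- df[order(match(df$time, time), match(df$lon, lon), match(df$lat, lat)), ]
  values <- array(df$value, dim = c(length(lat), length(lon), length(time)))
  grid_field(lat, lon, time, values, variable = variable)
}

# Daily date axis with leap days (Feb 29) removed.
daily_axis_noleap <- function(from_year, to_year) {
  d <- seq(as.Date(sprintf("%d-01-01", from_year)),
           as.Date(sprintf("%d-12-31", to_year)), by = "day")
  d[!(format(d, "%m-%d") == "02-29")]
}

# Index of the grid cell whose center is nearest (lat0, lon0).
nearest_cell <- function(field, lat0, lon0) {
  c(which.min(abs(field$lat - lat0)), which.min(abs(field$lon - lon0)))
}
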