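#' Assign a gridded series to point sites
#'
#' Gives every site (survey cluster) the daily series of the grid cell whose
#' center is nearest its coordinates — the grid-to-point rule used for
#' 0.25-degree reanalysis practice. A bilinear variant interpolates the four
#' surrounding cell centers instead.
#'
#' @param field a [grid_field()] with a daily time axis.
#' @param sites data frame with columns `site_id`, `lat`, `lon`.
#' @param date_range optional `Date` length-2 to restrict the series span.
#' @param method `"nearest"` (default) or `"bilinear"`.
#' @return A tibble in long form: `site_id`, `date`, `value`, `variable`.
#' @export
assign_site_series <- function(field, sites, date_range = NULL,
                               method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  m <- site_series_matrix(field, sites, date_range, method)
  tibble::tibble(
    site_id = rep(sites$site_id, each = length(m$dates)),
    date = rep(m$dates, times = nrow(sites)),
    value = as.vector(m$values),
    variable = field$variable
  )
}

# Matrix backend: days x sites values for a set of sites.
site_series_matrix <- function(field, sites, date_range = NULL,
                               method = "nearest") {
  bbox <- grid_bbox(field)
  out <- sites$lat < bbox["lat_min"] | sites$lat > bbox["lat_max"] |
    sites$lon < bbox["lon_min"] | sites$lon > bbox["lon_max"]
  if (any(out)) {
    stop("sites outside the grid bounding box: ",
         paste(sites$site_id[out], collapse = ", "), call. = FALSE)
  }
  keep <- rep(TRUE, length(field$time))
  if (!is.null(date_range)) {
    keep <- field$time >= date_range[1] & field$time <= date_range[2]
  }
  vals <- vapply(seq_len(nrow(sites)), function(s) {
    if (method == "nearest") {
      ij <- nearest_cell(field, sites$lat[s], sites$lon[s])
      field$values[ij[1], ij[2], keep]
    } else {
      bilinear_point(field, sites$lat[s], sites$lon[s], keep)
    }
  }, numeric(sum(keep)))
  list(dates = field$time[keep],
       values = matrix(vals, ncol = nrow(sites),
                       dimnames = list(NULL, sites$site_id)))
}

# Bilinear interpolation of one point across all (kept) time steps,
# clamped to the outermost cell centers.
bilinear_point <- function(field, lat0, lon0, keep = TRUE) {
  la <- field$lat; lo <- field$lon
  lat0 <- min(max(lat0, la[1]), la[length(la)])
  lon0 <- min(max(lon0, lo[1]), lo[length(lo)])
  i1 <- max(findInterval(lat0, la), 1L); i2 <- min(i1 + 1L, length(la))
  j1 <- max(findInterval(lon0, lo), 1L); j2 <- min(j1 + 1L, length(lo))
  wx <- if (i2 > i1) (lat0 - la[i1]) / (la[i2] - la[i1]) else 0
  wy <- if (j2 > j1) (lon0 - lo[j1]) / (lo[j2] - lo[j1]) else 0
  (1 - wx) * (1 - wy) * field$values[i1, j1, keep] +
    wx * (1 - wy) * field$values[i2, j1, keep] +
    (1 - wx) * wy * field$values[i1, j2, keep] +
    wx * wy * field$values[i2, j2, keep]
}

#' Trailing exposure window for one site series
#'
#' Computes the exposure over a trailing window ending the day before the
#' interview: the mean for temperature, the cumulative sum for
#' precipitation. Window lengths are calendar-agnostic day counts —
#' `round(window_months * 30.4375)` days — except the 12-month (annual)
#' window, fixed at exactly 365 days. With `lifetime = TRUE` and a birth
#' date inside the window, the window is truncated at the birth date (the
#' lookback used for children under one year old).
#'
#' @param series data frame with `date` and `value` columns (one site, one
#'   variable), daily and gapless over the window.
#' @param interview_date interview `Date`; the window excludes this day.
#' @param window_months window length in months: 1, 3, 6, 9 or 12.
#' @param statistic `"mean"` (temperature) or `"sum"` (precipitation).
#' @param birth_date optional `Date` used when `lifetime = TRUE`.
#' @param lifetime truncate the window at `birth_date`?
#' @return A one-row tibble: `window_months`, `n_days`, `value`, `complete`.
#'   `complete = FALSE` (with `value = NA`) flags insufficient history.
#' @export
window_exposure <- function(series, interview_date, window_months = 12,
                            statistic = c("mean", "sum"),
                            birth_date = NULL, lifetime = FALSE) {
  statistic <- match.arg(statistic)
  interview_date <- as.Date(interview_date)
  n_days <- window_days(window_months)
  ord <- order(series$date)
  dts <- as.Date(series$date)[ord]
  vals <- series$value[ord]
  # trailing window = last n_days observed days strictly before the
  # interview (the daily axis may be leap-free, so windows are day counts
  # on the axis, not calendar spans)
  before <- which(dts < interview_date)
  if (lifetime && !is.null(birth_date)) {
    before <- before[dts[before] >= as.Date(birth_date)]
  }
  sel <- utils::tail(before, n_days)
  # complete only if the series actually reaches the interview (within the
  # one-day slack a dropped leap day can introduce) and fills the window
  reaches <- length(sel) > 0 &&
    dts[sel[length(sel)]] >= interview_date - 2L
  full <- length(sel) == n_days ||
    (lifetime && !is.null(birth_date) && length(sel) > 0 &&
       dts[sel[1]] <= as.Date(birth_date) + 1L)
  if (!reaches || !full) {
    return(tibble::tibble(window_months = window_months,
                          n_days = length(sel),
                          value = NA_real_, complete = FALSE))
  }
  v <- if (statistic == "mean") mean(vals[sel]) else sum(vals[sel])
  tibble::tibble(window_months = window_months, n_days = length(sel),
                 value = v, complete = TRUE)
}

window_days <- function(window_months) {
  if (window_months == 12) 365L else as.integer(round(window_months * 30.4375))
}

#' Per-cluster exposure windows from a synthetic climate archive
#'
#' Vectorized workhorse joining clusters to the reference grid (nearest cell
#' center) and computing, for each cluster's interview date, the trailing
#' mean temperature and cumulative precipitation for each window plus the
#' trailing decadal (10-year) mean temperature used as a fixed covariate.
#'
#' @param climate a `synth_climate` from [generate_climate()].
#' @param sites data frame: `cluster_id`, `lat`, `lon`, `interview_date`.
#' @param windows integer vector of window lengths in months.
#' @return A tibble, one row per cluster x window: `cluster_id`,
#'   `window_months`, `mean_temperature`, `cumulative_precipitation`,
#'   `decadal_mean_temperature`.
#' @export
cluster_exposures <- function(climate, sites, windows = c(1, 3, 6, 9, 12)) {
  stopifnot(inherits(climate, "synth_climate"))
  s <- tibble::tibble(site_id = sites$cluster_id, lat = sites$lat,
                      lon = sites$lon)
  range_needed <- c(min(sites$interview_date) - 3651L,
                    max(sites$interview_date))
  tm <- site_series_matrix(climate$ref_temperature, s, range_needed)
  pm <- site_series_matrix(climate$ref_precipitation, s, range_needed)
  dts <- tm$dates
  cs_t <- apply(tm$values, 2, cumsum)
  cs_p <- apply(pm$values, 2, cumsum)
  end_idx <- findInterval(as.Date(sites$interview_date) - 1L, dts)
  out <- purrr::map_dfr(seq_along(windows), function(w) {
    nd <- window_days(windows[w])
    # on the 365-day axis, nd calendar days back ~ nd axis steps (leap-free)
    lo <- end_idx - nd
    if (any(lo < 0)) stop("insufficient reference history for the ",
                          windows[w], "-month window.", call. = FALSE)
    pick <- cbind(end_idx, seq_len(ncol(cs_t)))
    pick_lo <- cbind(pmax(lo, 1L), seq_len(ncol(cs_t)))
    sum_t <- cs_t[pick] - ifelse(lo == 0L, 0, cs_t[pick_lo])
    sum_p <- cs_p[pick] - ifelse(lo == 0L, 0, cs_p[pick_lo])
    tibble::tibble(cluster_id = sites$cluster_id, window_months = windows[w],
                   mean_temperature = sum_t / nd,
                   cumulative_precipitation = sum_p)
  })
  nd10 <- 3650L
  lo10 <- pmax(end_idx - nd10, 0L)
  pick <- cbind(end_idx, seq_len(ncol(cs_t)))
  pick_lo <- cbind(pmax(lo10, 1L), seq_len(ncol(cs_t)))
  dec <- (cs_t[pick] - ifelse(lo10 == 0L, 0, cs_t[pick_lo])) /
    (end_idx - lo10)
  dec_tbl <- tibble::tibble(cluster_id = sites$cluster_id,
                            decadal_mean_temperature = dec)
  dplyr::left_join(out, dec_tbl, by = "cluster_id")
}
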