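test_that("bilinear regridding is exact on constants and planes", {
  g <- toy_grid(matrix(5, 4, 4), lat = seq(0.5, 3.5), lon = seq(10.5, 13.5))
  r <- regrid_bilinear(g, 2)
  expect_true(all(r$values == 5))
  # plane a + b*lat + c*lon reproduced exactly at any target center
  lat <- seq(0.25, by = 0.5, length.out = 8)
  lon <- seq(20.25, by = 0.5, length.out = 8)
  plane <- outer(2 * lat, 0.7 * lon, "+") + 1
  gp <- toy_grid(plane, lat = lat, lon = lon)
  rp <- regrid_bilinear(gp, 1)
  expect_equal(rp$values[, , 1], outer(2 * rp$lat, 0.7 * rp$lon, "+") + 1,
               tolerance = 1e-12)
  # 2x2 corners (0,1,1,2): value at the midpoint is 1.0
  g2 <- toy_grid(matrix(c(0, 1, 1, 2), 2, 2), lat = c(0, 1), lon = c(0, 1))
  expect_equal(climanemia:::bilinear_point(g2, 0.5, 0.5), 1.0)
})

test_that("additive scaling removes a constant bias completely", {
  dates <- climanemia:::daily_axis_noleap(1990, 2020)
  nlat <- 2; nlon <- 2
  base <- array(rep(20 + 3 * cos(2 * pi * seq_along(dates) / 365),
                    each = nlat * nlon),
                dim = c(nlat, nlon, length(dates)))
  ref <- grid_field(1:2, 1:2, dates, base, variable = "temperature")
  gcm <- grid_field(1:2, 1:2, dates, base + 2, variable = "temperature")
  corr <- bias_correct(gcm, ref, calibration_window = c(1990, 2020))
  expect_equal(corr$values, ref$values, tolerance = 1e-10)
})

test_that("per-month injected biases are corrected to reference climatology", {
  cfg <- small_cfg()
  cl <- generate_climate(cfg)
  ref <- cl$ref_temperature
  g <- realize_gcm(cl, "gcm03", "ssp585")
  corr <- suppressWarnings(
    bias_correct(g, ref, calibration_window = cfg$baseline_window))
  yr <- as.integer(format(ref$time, "%Y"))
  mon <- as.integer(format(ref$time, "%m"))
  calib <- yr >= cfg$baseline_window[1] & yr <= cfg$baseline_window[2]
  for (m in 1:12) {
    sel <- calib & mon == m
    expect_lt(max(abs(apply(corr$values[, , sel], c(1, 2), mean) -
                        apply(ref$values[, , sel], c(1, 2), mean))), 1e-6)
  }
  # idempotence: correcting the corrected series is a no-op
  corr2 <- suppressWarnings(
    bias_correct(corr, ref, calibration_window = cfg$baseline_window))
  expect_equal(corr2$values, corr$values, tolerance = 1e-8)
  # additivity: correction leaves future-minus-baseline changes untouched
  fut <- yr >= 2025 & mon == 6
  bas <- calib & mon == 6
  expect_equal(mean(corr$values[, , fut]) - mean(corr$values[, , bas]),
               mean(g$values[, , fut]) - mean(g$values[, , bas]),
               tolerance = 1e-9)
})

test_that("calibration overlap rules are enforced", {
  dates <- climanemia:::daily_axis_noleap(2000, 2012)
  arr <- array(20, dim = c(1, 1, length(dates)))
  ref <- grid_field(1, 1, dates, arr, variable = "temperature")
  gcm <- grid_field(1, 1, dates, arr + 1, variable = "temperature")
  expect_warning(bias_correct(gcm, ref, calibration_window = c(2000, 2012)),
                 "overlap")
  expect_error(bias_correct(gcm, ref, calibration_window = c(2010, 2012)),
               "calibration")
})

test_that("city aggregation averages covered cell centers", {
  vals <- matrix(1:9, 3, 3)            # lat x lon, column-major: cell (i,j)
  g <- toy_grid(vals, lat = c(0.5, 1.5, 2.5), lon = c(0.5, 1.5, 2.5))
  b1 <- tibble::tibble(city_id = "one", country_code = "X", region = "R",
                       lon_min = 0, lon_max = 1, lat_min = 0, lat_max = 1)
  expect_equal(city_aggregate(g, b1)$value, vals[1, 1])
  # polygon covering cells with values 1 and 2 -> mean 1.5 (hand enumerated)
  b2 <- tibble::tibble(city_id = "two", country_code = "X", region = "R",
                       lon_min = 0, lon_max = 1, lat_min = 0, lat_max = 2)
  expect_equal(city_aggregate(g, b2)$value, mean(vals[1:2, 1]))
  # constant shift commutes with aggregation
  g2 <- toy_grid(vals + 7, lat = g$lat, lon = g$lon)
  expect_equal(city_aggregate(g2, b2)$value,
               city_aggregate(g, b2)$value + 7)
  # a polygon with no cell center falls back to the nearest cell
  b3 <- tibble::tibble(city_id = "sliver", country_code = "X", region = "R",
                       lon_min = 0.6, lon_max = 0.9, lat_min = 0.6, lat_max = 0.9)
  expect_message(v <- city_aggregate(g, b3)$value, "nearest")
  expect_equal(v, vals[1, 1])
  # degenerate polygons are rejected by city id
  b4 <- tibble::tibble(city_id = "bad", country_code = "X", region = "R",
                       lon_min = 2, lon_max = 1, lat_min = 0, lat_max = 1)
  expect_error(city_aggregate(g, b4), "bad")
})

test_that("ensemble ΔT recovers injected trends and scenario ordering", {
  cfg <- small_cfg(gcm_trend_spread = 0, n_gcms = 2, years = c(2000L, 2099L))
  cl <- generate_climate(cfg)
  b <- generate_boundaries(cfg)
  ens <- suppressWarnings(build_gcm_ensemble(cl, b))
  dt <- delta_t(ens)
  # linear ramp: ΔT(2090) analytic = trend/10 * (2090 - 2015)
  for (sc in cfg$scenarios) {
    got <- mean(dt$delta_t[dt$scenario == sc & dt$year == 2090])
    want <- cfg$warming_per_decade[[sc]] / 10 * (2090 - 2015)
    expect_lt(abs(got - want), 0.25)  # weather noise in a single annual mean
    got_dec <- mean(dt$delta_t[dt$scenario == sc & dt$year >= 2090])
    want_dec <- cfg$warming_per_decade[[sc]] / 10 * mean(2090:2099 - 2015)
    expect_lt(abs(got_dec - want_dec), 0.1)
  }
  # ΔT inside the baseline with zero trend averages to ~0
  base <- dt$delta_t[dt$year <= 2014]
  expect_lt(abs(mean(base)), 0.05)
  # scenario ordering in the 2090s
  d90 <- tapply(dt$delta_t[dt$year >= 2090], dt$scenario[dt$year >= 2090], mean)
  expect_true(d90[["ssp126"]] < d90[["ssp245"]] &
                d90[["ssp245"]] < d90[["ssp585"]])
})

test_that("city population table sums grid cells under the polygon", {
  w <- cached_world()
  pops <- suppressWarnings(build_city_population(w$population, w$boundaries))
  expect_equal(nrow(pops), nrow(w$boundaries))
  expect_equal(pops$under5_pop, pops$total_pop * pops$under5_proportion,
               tolerance = 1e-12)
  # hand-summed oracle for one city
  cty <- w$boundaries[3, ]
  f <- w$population$total_baseline
  ii <- which(f$lat >= cty$lat_min & f$lat <= cty$lat_max)
  jj <- which(f$lon >= cty$lon_min & f$lon <= cty$lon_max)
  expect_equal(pops$total_pop[3], sum(f$values[ii, jj, 1]), tolerance = 1e-9)
  # proportion arithmetic: a 0.15 share of a 1,000-person cell is 150
  pop2 <- w$population
  pop2$proportions$under5_proportion <- 0.15
  pop2$total_baseline$values[] <- 1000
  p2 <- suppressWarnings(build_city_population(pop2, w$boundaries))
  ncell <- p2$total_pop / 1000
  expect_equal(p2$under5_pop, ncell * 150, tolerance = 1e-12)
})
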