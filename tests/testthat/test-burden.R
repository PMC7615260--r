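make_fits <- function(countries, beta = log(1.138), se = 0.02, rate = 0.6376) {
  tibble::tibble(country_code = countries, beta = beta, se = se,
                 or = exp(beta), rate = rate,
                 rr = or_to_rr(exp(beta), rate),
                 erc = or_to_rr(exp(beta), rate) - 1, n = 1000L)
}

make_deltas <- function(cities, scenarios = "sspX", gcms = "g1",
                        years = 2090:2099, dt = 1) {
  d <- tidyr::expand_grid(gcm_id = gcms, scenario = scenarios,
                          city_id = cities, year = years)
  d$delta_t <- dt
  d
}

make_pops <- function(cities, countries, pop = 1e5) {
  tibble::tibble(city_id = cities, country_code = countries,
                 region = "R", under5_pop = pop)
}

test_that("the attribution kernel evaluates its closed form", {
  expect_equal(excess_cases(100000, 0.5, 0.138, 2), 13800)
  expect_equal(excess_cases(100000, 0.5, 0.138, 0), 0)
  expect_equal(excess_cases(100000, 0.5, 0, 2), 0)
  expect_equal(excess_cases(1000, 0.6, 0.05, -1), -30)  # cooling stays negative
  expect_error(excess_cases(-1, 0.5, 0.1, 1), "pop")
  expect_error(excess_cases(10, 1.5, 0.1, 1), "rate")
  expect_error(excess_cases(10, 0.5, -1.2, 1), "erc")
})

test_that("a constant-ΔT decade reproduces the hand-computed burden rate", {
  fits <- make_fits("C1")
  deltas <- make_deltas("city1")
  pops <- make_pops("city1", "C1")
  b <- attribute_burden(fits, deltas, pops, n_draws = 0)
  row <- tidy(b)[tidy(b)$scope_level == "city", ]
  # 1e5 * rate * erc * dT per 100k person-years
  want <- 1e5 * 0.6376 * (or_to_rr(1.138, 0.6376) - 1) * 1
  expect_equal(row$burden_per_100k, want, tolerance = 1e-9)
  expect_equal(row$excess_cases, 1e5 * 0.6376 * (or_to_rr(1.138, 0.6376) - 1),
               tolerance = 1e-6)
})

test_that("the point estimate is linear in ΔT across ensemble members", {
  fits <- make_fits("C1")
  pops <- make_pops("city1", "C1")
  d13 <- dplyr::bind_rows(make_deltas("city1", gcms = "g1", dt = 1),
                          make_deltas("city1", gcms = "g2", dt = 3))
  d2 <- make_deltas("city1", gcms = "g1", dt = 2)
  b13 <- tidy(attribute_burden(fits, d13, pops, n_draws = 0))
  b2 <- tidy(attribute_burden(fits, d2, pops, n_draws = 0))
  expect_equal(b13$burden_per_100k[b13$scope_level == "total"],
               b2$burden_per_100k[b2$scope_level == "total"],
               tolerance = 1e-12)
})

test_that("excess aggregates consistently from cities to countries to regions", {
  cities <- sprintf("city%d", 1:6)
  countries <- rep(c("C1", "C2", "C3"), each = 2)
  fits <- make_fits(c("C1", "C2", "C3"), beta = c(0.1, 0.15, 0.2),
                    rate = c(0.5, 0.6, 0.7))
  deltas <- make_deltas(cities, dt = rep(seq(0.5, 3, by = 0.5), times = 10))
  deltas$delta_t <- rep(seq(0.5, 3, by = 0.5), times = nrow(deltas) / 6)
  pops <- make_pops(cities, countries, pop = c(1e5, 2e5, 5e4, 3e5, 1e5, 2e5))
  pops$region <- rep(c("East", "West"), 3)
  b <- tidy(attribute_burden(fits, deltas, pops, n_draws = 0))
  tot <- b$excess_cases[b$scope_level == "total"]
  expect_equal(sum(b$excess_cases[b$scope_level == "city"]), tot,
               tolerance = 1e-9)
  expect_equal(sum(b$excess_cases[b$scope_level == "country"]), tot,
               tolerance = 1e-9)
  expect_equal(sum(b$excess_cases[b$scope_level == "region"]), tot,
               tolerance = 1e-9)
  # per-100k uses each scope's own baseline denominator
  east <- b[b$scope_level == "region" & b$scope == "East", ]
  expect_equal(east$burden_per_100k,
               1e5 * east$excess_cases / sum(pops$under5_pop[pops$region == "East"]),
               tolerance = 1e-9)
  # a missing country fit is an error naming the country
  expect_error(attribute_burden(make_fits(c("C1", "C2")), deltas, pops),
               "C3")
})

test_that("Monte Carlo eCIs collapse when uncertainty collapses", {
  fits <- make_fits("C1", se = 1e-12)
  deltas <- make_deltas("city1")
  pops <- make_pops("city1", "C1")
  b <- tidy(attribute_burden(fits, deltas, pops, n_draws = 200, seed = 4))
  row <- b[b$scope_level == "total", ]
  expect_lt(row$eci_high - row$eci_low, 1e-6 * max(1, row$burden_per_100k))
  expect_true(row$eci_low <= row$burden_per_100k &
                row$burden_per_100k <= row$eci_high)
})

test_that("pooled draw percentiles match the closed-form normal quantiles", {
  # burden is a monotone map of beta, so quantiles transform exactly
  beta <- log(1.138); se <- 0.05; rate <- 0.6376; dt <- 2
  fits <- make_fits("C1", beta = beta, se = se, rate = rate)
  deltas <- make_deltas("city1", dt = dt)
  pops <- make_pops("city1", "C1")
  eci <- monte_carlo_eci(fits, deltas, pops, n_draws = 10000, seed = 31,
                         scopes = "total")
  g <- function(b) 1e5 * rate * (or_to_rr(exp(b), rate) - 1) * dt
  expect_equal(eci$eci_low, g(qnorm(0.025, beta, se)), tolerance = 0.02)
  expect_equal(eci$eci_high, g(qnorm(0.975, beta, se)), tolerance = 0.02)
})

test_that("eCIs are reproducible under a fixed seed", {
  fits <- make_fits(c("C1", "C2"), beta = c(0.1, 0.2))
  deltas <- make_deltas(c("city1", "city2"))
  pops <- make_pops(c("city1", "city2"), c("C1", "C2"))
  b1 <- attribute_burden(fits, deltas, pops, n_draws = 100, seed = 10)
  b2 <- attribute_burden(fits, deltas, pops, n_draws = 100, seed = 10)
  expect_identical(tidy(b1), tidy(b2))
})

test_that("future-population variant reduces to the fixed variant for static grids", {
  fits <- make_fits("C1")
  deltas <- make_deltas("city1", scenarios = "ssp245", years = 2020:2099)
  pops <- make_pops("city1", "C1")
  pf <- tidyr::expand_grid(city_id = "city1", scenario = "ssp245",
                           decade = seq(2020, 2090, 10))
  pf$under5_pop <- 1e5   # constant in time = baseline
  b_fixed <- tidy(attribute_burden(fits, deltas, pops, n_draws = 0))
  b_proj <- tidy(attribute_burden(fits, deltas, pops, pops_future = pf,
                                  n_draws = 0))
  expect_equal(b_proj$burden_per_100k, b_fixed$burden_per_100k,
               tolerance = 1e-12)
  # growing population raises the projected-variant burden
  pf2 <- pf; pf2$under5_pop <- 1e5 * 1.1^((pf2$decade - 2020) / 10)
  b_grow <- tidy(attribute_burden(fits, deltas, pops, pops_future = pf2,
                                  n_draws = 0))
  late <- b_grow$decade == "2090s" & b_grow$scope_level == "total"
  expect_gt(b_grow$burden_per_100k[late], b_fixed$burden_per_100k[late])
})
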