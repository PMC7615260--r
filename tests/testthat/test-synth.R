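test_that("config validation rejects impossible study conditions", {
  expect_error(synth_config(baseline_prevalence = 1.2), "baseline_prevalence")
  expect_error(synth_config(baseline_prevalence = 0), "baseline_prevalence")
  expect_error(synth_config(mediation_frac_malnutrition = 0.6,
                            mediation_frac_malaria = 0.5), "mediation")
  expect_error(synth_config(n_gcms = 0), "n_gcms")
  expect_error(synth_config(years = c(2010, 2099), survey_years = c(2012, 2016)),
               "history")
  expect_error(synth_config(scenarios = c("ssp999")), "warming_per_decade")
})

test_that("default warming ramps reproduce the scenario 2090s warming targets", {
  cfg <- synth_config()
  ramp <- mean(2090:2099 - 2015) / 10
  expect_equal(unname(cfg$warming_per_decade[c("ssp126", "ssp245", "ssp585")] * ramp),
               c(1.1, 2.2, 4.0))
})

test_that("survey generator is deterministic and sized exactly by design", {
  cfg <- synth_config(seed = 1, n_countries = 2, clusters_per_country = 5,
                      children_per_cluster = 20, n_gcms = 2,
                      grid_resolution = 1.0, years = c(2000, 2016),
                      survey_years = c(2012, 2014))
  cl <- generate_climate(cfg)
  s1 <- generate_survey(cfg, cl)
  s2 <- generate_survey(cfg, cl)
  expect_equal(nrow(s1$children), 200L)
  expect_identical(s1$children, s2$children)
  expect_identical(s1$truth, s2$truth)
  # every cluster maps to exactly one site with coordinates, inside its country
  expect_true(all(s1$children$cluster_id %in% s1$sites$cluster_id))
  expect_equal(anyDuplicated(s1$sites$cluster_id), 0L)
  layout <- climanemia:::country_layout(cfg)
  j <- match(s1$sites$country_code, layout$country_code)
  expect_true(all(s1$sites$lon >= layout$lon_min[j] &
                    s1$sites$lon <= layout$lon_max[j]))
})

test_that("anemia status is a deterministic function of hemoglobin", {
  w <- cached_world()
  expect_identical(classify_anemia(w$survey$children$hb_adjusted),
                   w$survey$children$anemia_status)
})

test_that("marginal prevalence tracks the configured baseline at large n", {
  cfg <- synth_config(seed = 77, n_countries = 2, clusters_per_country = 100,
                      children_per_cluster = 250, years = c(2000, 2018),
                      survey_years = c(2012, 2015))
  sv <- suppressMessages(generate_survey(cfg))
  expect_gte(nrow(sv$children), 50000L)
  prev <- mean(sv$children$anemia_status != "none")
  expect_lt(abs(prev - cfg$baseline_prevalence), 0.02)
})

test_that("asset battery carries the latent wealth factor", {
  w <- cached_fit_world()
  wi <- wealth_index(w$survey$children)
  r <- cor(wi$wealth_score, w$survey$truth$latent_wealth)
  expect_gt(r, 0.8)
  # quintiles near-equal within survey
  tab <- table(wi$wealth_quintile[wi$country_code == "C01"])
  expect_lt(diff(range(tab)), 6)
})

test_that("climate generator injects recoverable biases and exact trends", {
  cfg <- small_cfg()
  cl <- generate_climate(cfg)
  # zero-bias, zero-spread member equals reference plus ramp exactly
  cfg0 <- small_cfg(gcm_bias_sd = 0, gcm_trend_spread = 0)
  cl0 <- generate_climate(cfg0)
  g <- realize_gcm(cl0, "gcm01", "ssp585")
  yr <- as.integer(format(g$time, "%Y"))
  ramp <- cl0$gcm_trend$trend_per_decade[
    cl0$gcm_trend$gcm_id == "gcm01" & cl0$gcm_trend$scenario == "ssp585"] / 10 *
    pmax(yr - 2015L, 0L)
  expect_equal(g$values,
               cl0$ref_temperature$values +
                 rep(ramp, each = length(g$lat) * length(g$lon)),
               tolerance = 1e-12)
  # injected monthly bias is visible in the raw calibration climatology
  g2 <- realize_gcm(cl, "gcm02", "ssp126")
  mon <- as.integer(format(g2$time, "%m"))
  calib <- yr >= cfg$baseline_window[1] & yr <= cfg$baseline_window[2]
  for (m in c(1L, 7L)) {
    est <- mean(g2$values[, , calib & mon == m]) -
      mean(cl$ref_temperature$values[, , calib & mon == m])
    truth <- cl$gcm_bias$bias_degc[cl$gcm_bias$gcm_id == "gcm02" &
                                     cl$gcm_bias$month == m]
    expect_lt(abs(est - truth), 0.01)
  }
})

test_that("climate truth sidecar round-trips through YAML", {
  cl <- cached_world()$climate
  f <- tempfile(fileext = ".yaml")
  write_climate_truth_yaml(cl, f)
  tr <- yaml::read_yaml(f)
  expect_equal(tr$gcm_bias$gcm02$Jul,
               cl$gcm_bias$bias_degc[cl$gcm_bias$gcm_id == "gcm02" &
                                       cl$gcm_bias$month == 7],
               tolerance = 1e-6)
})

test_that("population grids obey the under-5 proportion construction", {
  w <- cached_world()
  pop <- w$population
  u5 <- under5_grid(pop, 2030, "ssp245")
  tot <- pop$total_future[["ssp245"]]
  k <- match(2030, tot$time)
  pr <- pop$proportions
  pr <- pr[pr$scenario == "ssp245" & pr$decade == 2030, ]
  cellprop <- u5$values[, , 1] / tot$values[, , k]
  # each cell's ratio equals its country's proportion
  expect_true(all(abs(cellprop - min(pr$under5_proportion)) < 1e-12 |
                    abs(cellprop - max(pr$under5_proportion)) < 1e-12 |
                    vapply(as.vector(cellprop), function(x)
                      any(abs(x - pr$under5_proportion) < 1e-12), logical(1))))
  # proportions constant in time => constant under-5 share of country totals
  pop2 <- pop
  pop2$proportions$under5_proportion <- 0.15
  u5a <- under5_grid(pop2, 2020, "ssp126")
  u5b <- under5_grid(pop2, 2090, "ssp126")
  ta <- pop2$total_future[["ssp126"]]
  expect_equal(sum(u5a$values) / sum(ta$values[, , match(2020, ta$time)]), 0.15,
               tolerance = 1e-12)
  expect_equal(sum(u5b$values) / sum(ta$values[, , match(2090, ta$time)]), 0.15,
               tolerance = 1e-12)
})

test_that("generated files are byte-identical under a fixed seed", {
  cfg <- small_cfg()
  d1 <- file.path(tempdir(), "synthA"); d2 <- file.path(tempdir(), "synthB")
  cl <- generate_climate(cfg)
  s1 <- generate_survey(cfg, cl); s2 <- generate_survey(cfg, cl)
  write_survey_csv(s1, d1); write_survey_csv(s2, d2)
  expect_identical(unname(tools::md5sum(file.path(d1, "children.csv"))),
                   unname(tools::md5sum(file.path(d2, "children.csv"))))
  p1 <- generate_population(cfg); p2 <- generate_population(cfg)
  f1 <- file.path(d1, "pop.csv"); f2 <- file.path(d2, "pop.csv")
  write_grid_csv(p1$total_baseline, f1); write_grid_csv(p2$total_baseline, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("boundaries round-trip through GeoJSON", {
  b <- generate_boundaries(small_cfg())
  f <- tempfile(fileext = ".geojson")
  write_boundaries_geojson(b, f)
  b2 <- read_boundaries_geojson(f)
  expect_equal(as.data.frame(b2), as.data.frame(b), tolerance = 1e-12)
})
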