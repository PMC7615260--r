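#' Generate synthetic clustered survey microdata
#'
#' Draws a two-stage clustered child survey over the toy geography with the
#' covariate schema of household health surveys: child age band, sex, BMI,
#' malaria rapid-test result, bednet use, maternal age and education,
#' residence, household water/sanitation/floor/roof types and an asset
#' battery driven by a one-factor latent wealth variable. Anemia is drawn
#' from a mixed logistic model
#' \deqn{logit(p) = \alpha_{country} + u_{city} + \beta_{direct} T + g_m M_{maln} + g_a M_{mal} + \gamma'X}
#' where the annual temperature \eqn{T} is read from the generated reference
#' grid through the exposure module, and the two binary mediators
#' (malnutrition via a BMI threshold, malaria via the rapid test) are
#' generated so that the configured fractions of the total temperature
#' effect `beta_temp` are routed through them in the
#' difference-of-coefficients sense: each mediator's prevalence follows
#' \eqn{logit(p_M) = a + b (T - \bar T)} with
#' \eqn{b = f\,\beta_{temp} / (g\, p_M(1-p_M))} and mediator-on-outcome
#' log-odds \eqn{g = \log 2}, so \eqn{g \cdot dE[M]/dT \approx f\,\beta_{temp}}
#' at the domain-mean temperature. The direct coefficient is
#' \eqn{\beta_{temp}(1 - f_{maln} - f_{mal})}. Country intercepts are solved
#' numerically so each country's expected prevalence matches its target
#' (baseline prevalence plus a country offset). Hemoglobin is then drawn
#' within the severity band implied by a temperature-shifted conditional
#' severity distribution, making `anemia_status` a deterministic function of
#' `hb_adjusted`.
#'
#' @param config a [synth_config()].
#' @param climate optional pre-generated `synth_climate` (regenerated from
#'   `config` when missing).
#' @return A `synth_survey` list: `children` (tibble, one row per child),
#'   `sites` (cluster table with coordinates, city and interview date),
#'   `boundaries`, `country_covariates`, `truth` (generating parameters) and
#'   `config`.
#' @export
generate_survey <- function(config, climate = NULL) {
  validate_synth_config(config)
  if (is.null(climate)) climate <- generate_climate(config)
  set.seed(config$seed + 37L)
  layout <- country_layout(config)
  boundaries <- generate_boundaries(config)

  n_cl <- config$clusters_per_country
  n_ch <- config$children_per_cluster
  sites <- purrr::map_dfr(seq_len(nrow(layout)), function(i) {
    cc <- layout[i, ]
    tibble::tibble(
      cluster_id = sprintf("%s_cl%03d", cc$country_code, seq_len(n_cl)),
      country_code = cc$country_code, region = cc$region,
      lon = runif(n_cl, cc$lon_min, cc$lon_max),
      lat = runif(n_cl, cc$lat_min, cc$lat_max)
    )
  })
  # city = containing admin-2 rectangle
  sites$city_id <- vapply(seq_len(nrow(sites)), function(s) {
    b <- boundaries[boundaries$country_code == sites$country_code[s] &
                      sites$lon[s] >= boundaries$lon_min &
                      sites$lon[s] <= boundaries$lon_max &
                      sites$lat[s] >= boundaries$lat_min &
                      sites$lat[s] <= boundaries$lat_max, ]
    b$city_id[1]
  }, character(1))
  # fieldwork: each country starts in a random month and runs ~14 months,
  # so interview month and year vary within country
  start <- as.Date(sprintf("%d-%02d-01",
                           sample(config$survey_years[1]:(config$survey_years[2] - 1L),
                                  nrow(layout), replace = TRUE),
                           sample(1:12, nrow(layout), replace = TRUE)))
  sites$interview_date <- start[match(sites$country_code, layout$country_code)] +
    sample.int(420L, nrow(sites), replace = TRUE)

  expo <- cluster_exposures(climate, sites, windows = 12)
  sites$annual_temperature <- expo$mean_temperature
  sites$annual_precipitation <- expo$cumulative_precipitation
  sites$decadal_mean_temperature <- expo$decadal_mean_temperature

  country_covariates <- tibble::tibble(
    country_code = layout$country_code, region = layout$region,
    crop_production_index = rnorm(nrow(layout), 100, 15),
    gdp_per_capita = exp(rnorm(nrow(layout), log(1500), 0.4))
  )

  # --- children ---------------------------------------------------------
  n <- nrow(sites) * n_ch
  ch <- tibble::tibble(
    cluster_id = rep(sites$cluster_id, each = n_ch),
    child_id = sprintf("%s_c%03d", rep(sites$cluster_id, each = n_ch),
                       rep(seq_len(n_ch), nrow(sites)))
  )
  idx <- match(ch$cluster_id, sites$cluster_id)
  ch$country_code <- sites$country_code[idx]
  ch$region <- sites$region[idx]
  ch$city_id <- sites$city_id[idx]
  ch$interview_date <- sites$interview_date[idx]
  Tann <- sites$annual_temperature[idx]
  Tref <- mean(config$country_temp_range)

  ch$age_months <- sample.int(59L, n, replace = TRUE)
  ch$age_band <- factor(ifelse(ch$age_months < 24, "<2", "2-5"),
                        levels = c("2-5", "<2"))
  ch$sex <- factor(sample(c("male", "female"), n, TRUE),
                   levels = c("female", "male"))
  ch$itn_use <- rbinom(n, 1, 0.45) == 1
  ch$mother_age_band <- factor(
    sample(c("15-19", "20-29", "30-39", "40-49"), n, TRUE,
           prob = c(0.10, 0.45, 0.33, 0.12)),
    levels = c("20-29", "15-19", "30-39", "40-49"))
  ch$mother_education <- factor(
    sample(c("none", "primary", "secondary", "higher"), n, TRUE,
           prob = c(0.32, 0.38, 0.24, 0.06)),
    levels = c("none", "primary", "secondary", "higher"))
  urban <- rbinom(nrow(sites), 1, 0.3) == 1     # cluster-level residence
  ch$residence <- factor(ifelse(urban[idx], "urban", "rural"),
                         levels = c("urban", "rural"))
  ch$multiple_children <- factor(sample(c("singleton", "multiple"), n, TRUE,
                                        prob = c(0.55, 0.45)),
                                 levels = c("singleton", "multiple"))
  ch$water_source <- factor(sample(c("surface", "well", "piped", "other"),
                                   n, TRUE, prob = c(0.22, 0.4, 0.3, 0.08)),
                            levels = c("piped", "surface", "well", "other"))
  ch$sanitation <- factor(sample(c("none", "latrine", "flush", "other"),
                                 n, TRUE, prob = c(0.25, 0.5, 0.18, 0.07)),
                          levels = c("flush", "none", "latrine", "other"))
  ch$floor_material <- factor(sample(c("natural", "rudimentary", "finished", "other"),
                                     n, TRUE, prob = c(0.42, 0.2, 0.33, 0.05)),
                              levels = c("finished", "natural", "rudimentary", "other"))
  ch$roof_material <- factor(sample(c("natural", "rudimentary", "finished", "other"),
                                    n, TRUE, prob = c(0.3, 0.25, 0.4, 0.05)),
                             levels = c("finished", "natural", "rudimentary", "other"))

  # one-factor latent wealth driving the asset battery
  w <- rnorm(n)
  assets <- c("electricity", "car", "television", "refrigerator", "bicycle",
              "scooter", "mobile", "clean_fuel")
  a0 <- c(-0.4, -1.8, -0.8, -1.4, -0.2, -1.2, 0.6, -1.5)
  lam <- c(2.4, 2.0, 2.6, 2.4, 1.4, 1.8, 2.2, 2.4)
  for (k in seq_along(assets)) {
    ch[[paste0("asset_", assets[k])]] <- rbinom(n, 1, plogis(a0[k] + lam[k] * w))
  }

  ch$survey_month <- factor(format(ch$interview_date, "%m"),
                            levels = sprintf("%02d", 1:12))
  ch$survey_year <- factor(format(ch$interview_date, "%Y"))
  ch <- wealth_index(ch)

  # mediators and outcome
  g_med <- log(2)
  f_m <- config$mediation_frac_malnutrition
  f_a <- config$mediation_frac_malaria
  p_m0 <- config$malnutrition_prevalence
  p_a0 <- config$malaria_prevalence
  # first-order slopes; refined below so the population-limit
  # difference-of-coefficients proportions equal the config fractions
  b_m <- f_m * config$beta_temp / (g_med * p_m0 * (1 - p_m0))
  b_a <- f_a * config$beta_temp / (g_med * p_a0 * (1 - p_a0))
  beta_direct <- config$beta_temp * (1 - f_m - f_a)
  u_city <- rnorm(nrow(boundaries), sd = config$sd_city)
  names(u_city) <- boundaries$city_id
  gamma <- list(
    age = 0.35, male = 0.05, wealth = -0.15, itn = -0.05, rural = 0.10,
    multiple = 0.05,
    medu = c(none = 0, primary = -0.10, secondary = -0.25, higher = -0.40),
    mage = c("20-29" = 0, "15-19" = 0.08, "30-39" = -0.02, "40-49" = 0.02),
    water = c(piped = 0, surface = 0.12, well = 0.06, other = 0.04),
    sanit = c(flush = 0, none = 0.12, latrine = 0.05, other = 0.04),
    floor = c(finished = 0, natural = 0.10, rudimentary = 0.05, other = 0.03),
    roof = c(finished = 0, natural = 0.08, rudimentary = 0.04, other = 0.02),
    precip = -1e-4
  )
  lp0 <- beta_direct * (Tann - Tref) +
    gamma$age * (ch$age_band == "<2") + gamma$male * (ch$sex == "male") +
    gamma$wealth * w + gamma$itn * ch$itn_use +
    gamma$rural * (ch$residence == "rural") +
    gamma$multiple * (ch$multiple_children == "multiple") +
    gamma$medu[as.character(ch$mother_education)] +
    gamma$mage[as.character(ch$mother_age_band)] +
    gamma$water[as.character(ch$water_source)] +
    gamma$sanit[as.character(ch$sanitation)] +
    gamma$floor[as.character(ch$floor_material)] +
    gamma$roof[as.character(ch$roof_material)] +
    gamma$precip * (sites$annual_precipitation[idx] -
                      mean(sites$annual_precipitation)) +
    u_city[ch$city_id]

  delta_c <- rnorm(nrow(layout), sd = config$sd_country_prev)
  target_c <- plogis(qlogis(config$baseline_prevalence) + delta_c)
  # recenter so the equal-weight marginal prevalence equals the baseline
  target_c <- pmin(pmax(
    target_c + (config$baseline_prevalence - mean(target_c)), 0.02), 0.98)
  if (any(!is.finite(qlogis(target_c)) | target_c <= 0 | target_c >= 1)) {
    stop("a country target prevalence falls outside (0, 1); ",
         "check `baseline_prevalence`.", call. = FALSE)
  }

  # Population-limit calibration. Three generating knobs are tuned against
  # the exact large-sample coefficients of the fitted (misspecified) models,
  # computed from the generating probabilities by probability-weighted IRLS:
  #   * beta_direct, so the MAIN model's temperature coefficient (which
  #     adjusts for continuous BMI and thereby blocks most of the
  #     malnutrition-threshold pathway) equals beta_temp — the config OR is
  #     the estimand of the pooled fit;
  #   * the mediator-temperature slopes b_m / b_a, so the
  #     difference-of-coefficients mediated proportions of the mediation
  #     models (which drop BMI) equal the config fractions.
  # The BMI noise is drawn first so the malnutrition indicator is a
  # deterministic function of the current slope inside the loop.
  sd_bmi <- 1.5
  z_bmi <- rnorm(n)
  ch$city_fac <- factor(ch$city_id)
  ccv <- country_covariates[match(ch$country_code,
                                  country_covariates$country_code), ]
  dd <- ch
  dd$mean_temperature <- Tann
  dd$cumulative_precipitation <- sites$annual_precipitation[idx]
  dd$decadal_mean_temperature <- sites$decadal_mean_temperature[idx]
  dd$crop_production_index <- ccv$crop_production_index
  dd$gdp_per_capita <- ccv$gdp_per_capita
  med_covs <- intersect(setdiff(assoc_covariates(), "bmi"), names(dd))
  for (v in med_covs) if (is.factor(dd[[v]])) dd[[v]] <- droplevels(dd[[v]])
  med_covs <- med_covs[vapply(med_covs, function(v) {
    !is.factor(dd[[v]]) || nlevels(dd[[v]]) > 1L
  }, logical(1))]
  fe <- if (nlevels(droplevels(ch$city_fac)) > 1L) "city_fac" else NULL
  Xmed <- model.matrix(reformulate(c("mean_temperature", med_covs, fe)),
                       data = dd)
  kT <- which(colnames(Xmed) == "mean_temperature")
  country_rows <- split(seq_len(n), ch$country_code)

  solve_alpha <- function(m1, p2) {
    a <- vapply(layout$country_code, function(ccode) {
      rows <- country_rows[[ccode]]
      tgt <- target_c[match(ccode, layout$country_code)]
      base <- lp0[rows] + g_med * m1[rows]
      uniroot(function(a) {
        mean((1 - p2[rows]) * plogis(a + base) +
               p2[rows] * plogis(a + base + g_med)) - tgt
      }, lower = -20, upper = 20)$root
    }, numeric(1))
    names(a) <- layout$country_code
    a
  }
  pop_fit <- function(X, y, w, start = NULL) {
    fast_logit_fit(X, y, w = w, start = start)
  }
  calibrate <- abs(config$beta_temp) > 1e-12 && n > 5L * (ncol(Xmed) + 2L)
  n_iter <- if (calibrate) 5L else 1L
  achieved <- c(malnutrition = NA_real_, malaria = NA_real_,
                main_beta = NA_real_)
  st_main <- st_te <- st_de1 <- st_de2 <- NULL
  p1 <- p2 <- m1 <- bmi_raw <- alpha_c <- NULL
  for (it in seq_len(n_iter)) {
    p1 <- plogis(qlogis(p_m0) + b_m * (Tann - Tref))
    p2 <- plogis(qlogis(p_a0) + b_a * (Tann - Tref))
    bmi_raw <- 15 - sd_bmi * qnorm(p1) + sd_bmi * z_bmi
    m1 <- as.numeric(bmi_raw < 15)
    alpha_c <- solve_alpha(m1, p2)
    if (!calibrate) break
    al <- alpha_c[ch$country_code]
    pY <- function(m1v, m2v) plogis(al + lp0 + g_med * (m1v + m2v))
    ok <- tryCatch({
      ybar <- (1 - p2) * pY(m1, 0) + p2 * pY(m1, 1)
      # main model: mediation design + continuous BMI
      Xmain <- cbind(Xmed, bmi = bmi_raw)
      st_main <- pop_fit(Xmain, ybar, rep(1, n), start = st_main)
      te_main <- st_main[kT]
      # mediation TE / DE models (no BMI)
      st_te <- pop_fit(Xmed, ybar, rep(1, n), start = st_te)
      te <- st_te[kT]
      st_de1 <- pop_fit(cbind(Xmed, med = m1), ybar, rep(1, n), start = st_de1)
      de1 <- st_de1[kT]
      X2 <- rbind(cbind(Xmed, med = 0), cbind(Xmed, med = 1))
      y2 <- c(pY(m1, 0), pY(m1, 1))
      st_de2 <- pop_fit(X2, y2, c(1 - p2, p2), start = st_de2)
      de2 <- st_de2[kT]
      achieved <- c(malnutrition = unname((te - de1) / te),
                    malaria = unname((te - de2) / te),
                    main_beta = unname(te_main))
      TRUE
    }, error = function(e) {
      message("generator calibration fit failed (", conditionMessage(e),
              "); keeping current parameters.")
      FALSE
    })
    if (!ok) break
    if (it < n_iter) {
      ratio_main <- config$beta_temp / achieved[["main_beta"]]
      if (is.finite(ratio_main) && ratio_main > 0) {
        beta_direct <- beta_direct +
          config$beta_temp - achieved[["main_beta"]]
        lp0 <- lp0 + (config$beta_temp - achieved[["main_beta"]]) *
          (Tann - Tref)
      }
      if (f_m > 0 && is.finite(achieved[1]) && achieved[1] > 1e-6) {
        b_m <- b_m * min(max(f_m / achieved[1], 0.2), 5)
      }
      if (f_a > 0 && is.finite(achieved[2]) && achieved[2] > 1e-6) {
        b_a <- b_a * min(max(f_a / achieved[2], 0.2), 5)
      }
    }
  }
  ch$city_fac <- NULL

  ch$bmi <- round(bmi_raw, 2)
  maln <- as.integer(ch$bmi < 15)
  malaria <- rbinom(n, 1, p2)
  ch$malaria_rdt <- factor(ifelse(malaria == 1, "positive", "negative"),
                           levels = c("negative", "positive"))
  p <- plogis(alpha_c[ch$country_code] + lp0 + g_med * maln + g_med * malaria)
  anemia <- rbinom(n, 1, p)

  # severity conditional on anemia: cumulative logit shifted by temperature
  base_cond <- c(severe = 0.0544, moderate = 0.5543, mild = 0.3913)
  cum1 <- plogis(qlogis(base_cond[1]) + config$severity_temp_shift * (Tann - Tref))
  cum2 <- plogis(qlogis(base_cond[1] + base_cond[2]) +
                   config$severity_temp_shift * (Tann - Tref))
  u <- runif(n)
  hb <- numeric(n)
  sev <- anemia == 1 & u < cum1
  mod <- anemia == 1 & u >= cum1 & u < cum2
  mil <- anemia == 1 & u >= cum2
  hb[sev] <- runif(sum(sev), 4, 7)
  hb[mod] <- runif(sum(mod), 7, 10)
  hb[mil] <- runif(sum(mil), 10, 11)
  hb[anemia == 0] <- 11 + 5 * stats::rbeta(sum(anemia == 0), 1.2, 2.5)
  ch$hb_adjusted <- round(pmin(hb, 18), 1)
  # rounding to 0.1 g/dL must not cross a class boundary
  ch$hb_adjusted[anemia == 0 & ch$hb_adjusted < 11] <- 11.0
  ch$hb_adjusted[mil & ch$hb_adjusted >= 11] <- 10.9
  ch$hb_adjusted[mod & ch$hb_adjusted >= 10] <- 9.9
  ch$hb_adjusted[sev & ch$hb_adjusted >= 7] <- 6.9
  ch$anemia_status <- classify_anemia(ch$hb_adjusted)

  truth <- list(
    beta_temp = config$beta_temp, beta_direct = beta_direct,
    mediator_on_outcome = g_med,
    mediator_temp_slopes = c(malnutrition = b_m, malaria = b_a),
    mediated_fractions = c(malnutrition = f_m, malaria = f_a),
    mediated_fractions_population_limit = achieved,
    alpha_country = alpha_c,
    target_prevalence = setNames(target_c, layout$country_code),
    u_city = u_city, latent_wealth = w, gamma = gamma, temp_ref = Tref
  )
  structure(list(children = ch, sites = sites, boundaries = boundaries,
                 country_covariates = country_covariates, truth = truth,
                 config = config),
            class = "synth_survey")
}

#' @export
print.synth_survey <- function(x, ...) {
  cat(sprintf("<synth_survey: %d children, %d clusters, %d countries, prevalence %.3f>\n",
              nrow(x$children), nrow(x$sites), x$config$n_countries,
              mean(x$children$anemia_status != "none")))
  invisible(x)
}

#' Write survey microdata and cluster sites as CSV
#'
#' @param survey a `synth_survey`.
#' @param dir output directory (created if needed); writes
#'   `children.csv` and `sites.csv` with ISO-8601 dates.
#' @return The directory path, invisibly.
#' @export
write_survey_csv <- function(survey, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ch <- survey$children
  ch$interview_date <- format(ch$interview_date, "%Y-%m-%d")
  write.csv(ch, file.path(dir, "children.csv"), row.names = FALSE)
  st <- survey$sites
  st$interview_date <- format(st$interview_date, "%Y-%m-%d")
  write.csv(st, file.path(dir, "sites.csv"), row.names = FALSE)
  invisible(dir)
}
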