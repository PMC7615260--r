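test_that("hemoglobin thresholds partition the severity axis", {
  expect_equal(as.character(classify_anemia(c(6.9, 7.0, 9.9, 10.0, 10.5, 10.9, 11.0, 14))),
               c("severe", "moderate", "moderate", "mild", "mild", "mild",
                 "none", "none"))
  expect_warning(out <- classify_anemia(c(1.5, 8, 25)), "invalid")
  expect_true(is.na(out[1]) && is.na(out[3]) && out[2] == "moderate")
})

test_that("odds-to-risk conversion obeys its closed form and limits", {
  expect_equal(or_to_rr(1.138, 0), 1.138)            # rare-outcome limit
  expect_equal(or_to_rr(1.138, 1), 1)                # universal-outcome limit
  expect_equal(or_to_rr(1.138, 0.6376),
               1.138 / (1 - 0.6376 + 0.6376 * 1.138), tolerance = 1e-15)
  expect_error(or_to_rr(-1, 0.5), "positive")
  expect_error(or_to_rr(1.1, 1.5), "rate")
  # RR strictly between 1 and OR for common outcomes; monotone in rate
  set.seed(3)
  or <- exp(runif(500, -1.5, 1.5)); rate <- runif(500, 0.01, 0.99)
  rr <- or_to_rr(or, rate)
  up <- or > 1
  expect_true(all(rr[up] > 1 & rr[up] < or[up]))
  expect_true(all(rr[!up] < 1 & rr[!up] > or[!up]))
  rates <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(or_to_rr(1.5, rates)) < 0))
})

test_that("wealth index handles degenerate asset batteries deterministically", {
  d <- data.frame(country_code = "X",
                  asset_a = rep(1, 20), asset_b = rep(0, 20))
  expect_warning(out <- wealth_index(d), "constant")
  expect_true(all(out$wealth_quintile == "middle"))
  # a single binary asset collapses quintiles to two deterministic groups
  d2 <- data.frame(country_code = "X", asset_a = rep(c(0, 1), each = 25))
  out2 <- wealth_index(d2)
  expect_equal(length(unique(out2$wealth_score)), 2L)
  expect_true(all(out2$wealth_score[d2$asset_a == 1] >
                    out2$wealth_score[d2$asset_a == 0]))
  # rank-based cuts keep quintiles near-equal despite ties
  expect_true(all(table(out2$wealth_quintile) == 10))
})

test_that("association fit returns a coherent effect summary", {
  w <- cached_fit_world()
  f <- suppressWarnings(
    fit_association(w$survey$children, w$exposures,
                    w$survey$country_covariates, method = "glm"))
  expect_s3_class(f, "assoc_fit")
  expect_equal(f$or_per_degc, exp(f$beta_temp))
  expect_true(f$or_ci[1] < f$or_ci[2])
  expect_equal(f$erc, f$rr_per_degc - 1)
  expect_true(f$rr_per_degc < f$or_per_degc)  # common outcome, OR > 1 here
  expect_equal(f$n, nrow(w$survey$children))
  # generating effect is inside a wide sanity band at this n
  expect_gt(f$beta_temp, w$cfg$beta_temp - 4 * f$se_beta)
  expect_lt(f$beta_temp, w$cfg$beta_temp + 4 * f$se_beta)
  td <- tidy(f); gl <- glance(f)
  expect_equal(nrow(td), 1L)
  expect_named(gl, c("n", "n_clusters", "method", "converged", "model_ic",
                     "window_months"))
  # glmer engine agrees with the fallback at this scale
  fg <- suppressWarnings(
    fit_association(w$survey$children, w$exposures,
                    w$survey$country_covariates, method = "glmer", nAGQ = 0L))
  expect_lt(abs(fg$beta_temp - f$beta_temp), 3 * f$se_beta)
})

test_that("scoped fits and severity outcomes restrict rows as specified", {
  w <- cached_fit_world()
  fc <- suppressWarnings(
    fit_association(w$survey$children, w$exposures,
                    w$survey$country_covariates, scope = "country",
                    scope_value = "C02", method = "glm"))
  expect_equal(fc$n, sum(w$survey$children$country_code == "C02"))
  fm <- suppressWarnings(
    fit_association(w$survey$children, w$exposures,
                    w$survey$country_covariates, outcome = "moderate",
                    method = "glm"))
  st <- w$survey$children$anemia_status
  expect_equal(fm$n, sum(st %in% c("none", "moderate")))
  expect_equal(fm$rate, mean(st[st %in% c("none", "moderate")] == "moderate"),
               tolerance = 1e-12)
  expect_error(fit_association(w$survey$children, w$exposures,
                               scope = "country"), "scope_value")
})

test_that("country fit table feeds the burden module", {
  w <- cached_fit_world()
  fits <- suppressWarnings(
    fit_country_associations(w$survey$children, w$exposures,
                             w$survey$country_covariates, method = "glm"))
  expect_equal(fits$country_code, sprintf("C%02d", 1:4))
  expect_true(all(fits$se > 0))
  expect_equal(fits$erc, fits$rr - 1)
  expect_equal(fits$rr, or_to_rr(fits$or, fits$rate))
})

test_that("exposure-response curve flags nonlinearity only when present", {
  w <- cached_fit_world()
  ec <- suppressWarnings(
    er_curve(w$survey$children, w$exposures, w$survey$country_covariates))
  expect_s3_class(ec, "er_curve")
  expect_true(ec$p_linearity >= 0 && ec$p_linearity <= 1)
  expect_true(all(is.finite(ec$curve$log_odds)))
  expect_true(all(ec$curve$lo <= ec$curve$log_odds &
                    ec$curve$log_odds <= ec$curve$hi))
  expect_equal(nrow(tidy(ec)), 50L)
})

test_that("linearity test keeps its size on linear data and has power on curvature", {
  # small replicated check: under the linear generator the spline should
  # rarely be preferred; with an injected quadratic signal it must be found
  w <- cached_fit_world()
  d <- climanemia:::assoc_model_frame(w$survey$children, w$exposures,
                                      w$survey$country_covariates, 12, "any")
  set.seed(5)
  ps_null <- replicate(25, {
    d$outcome <- rbinom(nrow(d), 1,
                        plogis(-0.5 + 0.12 * (d$mean_temperature - 23)))
    f1 <- glm(outcome ~ mean_temperature + residence, data = d,
              family = quasibinomial())
    f2 <- glm(outcome ~ splines::ns(mean_temperature, 3) + residence, data = d,
              family = quasibinomial())
    anova(f1, f2, test = "F")[["Pr(>F)"]][2]
  })
  expect_gte(mean(ps_null > 0.05), 0.8)
  ps_quad <- replicate(10, {
    d$outcome <- rbinom(nrow(d), 1,
                        plogis(-0.3 + 0.12 * (d$mean_temperature - 23) -
                                 0.08 * (d$mean_temperature - 23)^2))
    f1 <- glm(outcome ~ mean_temperature + residence, data = d,
              family = quasibinomial())
    f2 <- glm(outcome ~ splines::ns(mean_temperature, 3) + residence, data = d,
              family = quasibinomial())
    anova(f1, f2, test = "F")[["Pr(>F)"]][2]
  })
  expect_gte(mean(ps_quad < 0.05), 0.9)
})
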