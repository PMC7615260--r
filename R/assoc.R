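#' Classify anemia severity from altitude-adjusted hemoglobin
#'
#' Applies the WHO under-5 severity thresholds to altitude-adjusted Hb
#' (g/dL): severe below 7.0, moderate 7.0 to below 10.0, mild 10.0 to below
#' 11.0, none at 11.0 and above. Half-open intervals partition the axis.
#' Values outside the plausible 2-20 g/dL range are flagged invalid (`NA`)
#' with a warning, for complete-case exclusion downstream.
#'
#' @param hb_adjusted numeric vector of altitude-adjusted Hb in g/dL.
#' @return A factor with levels `none`, `mild`, `moderate`, `severe`.
#' @export
classify_anemia <- function(hb_adjusted) {
  bad <- !is.na(hb_adjusted) & (hb_adjusted < 2 | hb_adjusted > 20)
  if (any(bad)) {
    warning(sum(bad), " Hb value(s) outside 2-20 g/dL flagged invalid.",
            call. = FALSE)
    hb_adjusted[bad] <- NA_real_
  }
  cut(hb_adjusted, breaks = c(-Inf, 7, 10, 11, Inf), right = FALSE,
      labels = c("severe", "moderate", "mild", "none")) |>
    factor(levels = c("none", "mild", "moderate", "severe"))
}

#' Household wealth index from asset indicators
#'
#' First principal component of the standardized household asset battery,
#' computed within survey (PCA loadings are survey-specific), sign-oriented
#' so that owning more assets gives a higher score, and cut into
#' near-equal-sized quintiles at the 20/40/60/80th percentiles within
#' survey (ties broken deterministically by row order). Constant asset
#' columns are dropped with a warning; a fully degenerate survey (all
#' households identical) gets every household assigned `middle`.
#'
#' @param data data frame containing the asset indicator columns and a
#'   survey identifier column.
#' @param survey_id name of the survey identifier column (default
#'   `"country_code"`: one survey per country in the synthetic world).
#' @param asset_cols character vector of asset column names; defaults to
#'   every column starting with `"asset_"`.
#' @return `data` with `wealth_score` and `wealth_quintile` (factor
#'   `poorest` to `richest`) columns appended, as a tibble.
#' @export
wealth_index <- function(data, survey_id = "country_code", asset_cols = NULL) {
  if (is.null(asset_cols)) {
    asset_cols <- grep("^asset_", names(data), value = TRUE)
  }
  if (length(asset_cols) < 1L) stop("no asset indicator columns found.", call. = FALSE)
  data <- tibble::as_tibble(data)
  data$wealth_score <- NA_real_
  labs <- c("poorest", "poorer", "middle", "richer", "richest")
  data$wealth_quintile <- factor(rep(NA_character_, nrow(data)), levels = labs)
  for (sv in unique(data[[survey_id]])) {
    rows <- which(data[[survey_id]] == sv)
    x <- as.matrix(data[rows, asset_cols])
    keep <- apply(x, 2, function(v) stats::var(v) > 0)
    if (!all(keep)) {
      warning("survey ", sv, ": dropped constant asset column(s): ",
              paste(asset_cols[!keep], collapse = ", "), call. = FALSE)
    }
    if (!any(keep)) {
      data$wealth_score[rows] <- 0
      data$wealth_quintile[rows] <- "middle"
      next
    }
    xs <- scale(x[, keep, drop = FALSE])
    pc <- prcomp(xs, center = FALSE, scale. = FALSE)
    score <- pc$x[, 1]
    if (stats::cor(score, rowSums(x[, keep, drop = FALSE])) < 0) score <- -score
    data$wealth_score[rows] <- score
    r <- rank(score, ties.method = "first")
    data$wealth_quintile[rows] <- labs[ceiling(5 * r / length(r))]
  }
  data$wealth_quintile <- factor(as.character(data$wealth_quintile), levels = labs)
  data
}

#' Convert an odds ratio to a risk ratio given outcome prevalence
#'
#' For a common outcome the odds ratio overstates the risk ratio; with
#' baseline prevalence `rate` the conversion is
#' \deqn{RR = OR / (1 - Rate + Rate \times OR).}
#' The map is monotone in OR, so it applies to confidence bounds as well as
#' point estimates. At `rate = 0` the RR equals the OR; at `rate = 1` it is 1.
#'
#' @param or_value odds ratio(s), positive.
#' @param rate outcome prevalence(s) in `[0, 1]`, recycled against `or_value`.
#' @return Risk ratio(s).
#' @export
or_to_rr <- function(or_value, rate) {
  if (any(or_value <= 0, na.rm = TRUE)) {
    stop("`or_value` must be positive.", call. = FALSE)
  }
  if (any(rate < 0 | rate > 1, na.rm = TRUE)) {
    stop("`rate` must lie in [0, 1].", call. = FALSE)
  }
  or_value / (1 - rate + rate * or_value)
}

# Default fixed-covariate set of the main association model.
assoc_covariates <- function() {
  c("age_band", "sex", "bmi", "itn_use", "residence", "multiple_children",
    "mother_age_band", "mother_education", "wealth_quintile",
    "water_source", "sanitation", "floor_material", "roof_material",
    "cumulative_precipitation", "decadal_mean_temperature",
    "crop_production_index", "gdp_per_capita", "survey_month", "survey_year")
}

# Assemble the complete-case model frame: records + annual exposure +
# country-level covariates + wealth quintile + binary outcome.
assoc_model_frame <- function(records, exposures, country_covariates = NULL,
                              window_months = 12,
                              outcome = c("any", "mild", "moderate", "severe"),
                              covariates = assoc_covariates()) {
  outcome <- match.arg(outcome)
  ex <- exposures[exposures$window_months == window_months, ]
  if (nrow(ex) == 0L) {
    stop("no exposure rows for window_months = ", window_months, call. = FALSE)
  }
  d <- dplyr::left_join(tibble::as_tibble(records), ex, by = "cluster_id")
  if (!is.null(country_covariates)) {
    d <- dplyr::left_join(
      d, country_covariates[, c("country_code", "crop_production_index",
                                "gdp_per_capita")], by = "country_code")
  }
  if (!"wealth_quintile" %in% names(d) && any(grepl("^asset_", names(d)))) {
    d <- wealth_index(d)
  }
  if (outcome == "any") {
    d$outcome <- as.integer(d$anemia_status != "none")
  } else {
    d <- d[d$anemia_status %in% c("none", outcome), ]
    d$outcome <- as.integer(d$anemia_status == outcome)
  }
  covariates <- intersect(covariates, names(d))
  keep <- c("outcome", "mean_temperature", covariates, "city_id",
            "cluster_id", "country_code", "region")
  d <- d[, intersect(keep, names(d))]
  n0 <- nrow(d)
  d <- d[complete.cases(d), ]
  if (nrow(d) < n0) {
    message(n0 - nrow(d), " incomplete rows excluded (complete-case analysis).")
  }
  # drop factor covariates left with a single observed level
  for (v in covariates) {
    if (is.factor(d[[v]])) {
      d[[v]] <- droplevels(d[[v]])
      if (nlevels(d[[v]]) < 2L) d[[v]] <- NULL
    }
  }
  d
}

#' Fit the temperature-anemia mixed-effects logistic model
#'
#' Estimates the log-odds of childhood anemia per +1 degC of trailing annual
#' mean temperature with a multivariable logistic model: fixed effects for
#' the child, maternal, household, climate and country-level covariates
#' (plus survey month and year), and a random intercept for city. The
#' default engine is maximum likelihood with a Laplace approximation
#' (`lme4::glmer`); `method = "glm"` fits the fixed-effects-only model with
#' cluster-robust (city-clustered) standard errors, a fast fallback for
#' small fixtures and resampling loops. Severity-specific outcomes contrast
#' one severity level against non-anemic children. The fitted odds ratio is
#' converted to a risk ratio via [or_to_rr()] at the prevalence observed in
#' the fitted scope, giving the excess risk coefficient `erc = rr - 1`.
#'
#' @param records child records (see [generate_survey()]).
#' @param exposures per-cluster exposure table from [cluster_exposures()].
#' @param country_covariates optional country-level covariate table.
#' @param window_months exposure window (months); the main model uses 12.
#' @param outcome `"any"` anemia or one severity level vs non-anemic.
#' @param scope `"pooled"`, `"region"` or `"country"`; with non-pooled
#'   scopes, `scope_value` selects the unit.
#' @param scope_value region or country code for non-pooled scopes.
#' @param method `"glmer"` (Laplace) or `"glm"` (cluster-robust fallback).
#' @param nAGQ integer passed to `lme4::glmer`; `0` gives a faster, slightly
#'   cruder fit for very large inputs.
#' @param covariates character vector of fixed covariates to adjust for.
#' @param min_rows minimum complete-case rows required to fit.
#' @return An `assoc_fit` object; see [tidy.assoc_fit()] / [glance.assoc_fit()].
#' @export
fit_association <- function(records, exposures, country_covariates = NULL,
                            window_months = 12,
                            outcome = c("any", "mild", "moderate", "severe"),
                            scope = c("pooled", "region", "country"),
                            scope_value = NULL,
                            method = c("glmer", "glm"), nAGQ = 1L,
                            covariates = assoc_covariates(), min_rows = 50) {
  outcome <- match.arg(outcome)
  scope <- match.arg(scope)
  method <- match.arg(method)
  if (scope != "pooled") {
    if (is.null(scope_value)) stop("`scope_value` required for scope = ", scope,
                                   call. = FALSE)
    col <- if (scope == "region") "region" else "country_code"
    records <- records[records[[col]] == scope_value, ]
  }
  d <- assoc_model_frame(records, exposures, country_covariates,
                         window_months, outcome, covariates)
  if (nrow(d) < min_rows) {
    stop("only ", nrow(d), " complete-case rows in scope; need >= ", min_rows,
         call. = FALSE)
  }
  covs <- setdiff(intersect(covariates, names(d)),
                  c("outcome", "mean_temperature"))
  rhs <- paste(c("mean_temperature", covs), collapse = " + ")
  if (method == "glmer") {
    fml <- as.formula(paste("outcome ~", rhs, "+ (1 | city_id)"))
    fit <- lme4::glmer(fml, data = d, family = binomial(), nAGQ = nAGQ,
                       control = lme4::glmerControl(
                         optimizer = "bobyqa", calc.derivs = FALSE,
                         optCtrl = list(maxfun = 1e5)))
    beta <- lme4::fixef(fit)[["mean_temperature"]]
    se <- sqrt(diag(as.matrix(vcov(fit)))[["mean_temperature"]])
    coefs <- lme4::fixef(fit)
    ic <- AIC(fit)
    conv <- length(fit@optinfo$conv$lme4$messages) == 0L
  } else {
    fml <- as.formula(paste("outcome ~", rhs))
    fit <- glm(fml, data = d, family = binomial())
    if (!fit$converged) {
      stop("glm did not converge for scope ", scope, call. = FALSE)
    }
    vc <- sandwich::vcovCL(fit, cluster = d$city_id)
    beta <- coef(fit)[["mean_temperature"]]
    se <- sqrt(vc["mean_temperature", "mean_temperature"])
    coefs <- coef(fit)
    ic <- AIC(fit)
    conv <- fit$converged
  }
  rate <- mean(d$outcome)
  or <- exp(beta)
  ci_or <- exp(beta + c(-1, 1) * qnorm(0.975) * se)
  structure(list(
    beta_temp = beta, se_beta = se, or_per_degc = or,
    or_ci = ci_or, rr_per_degc = or_to_rr(or, rate),
    rr_ci = or_to_rr(ci_or, rate), rate = rate,
    erc = or_to_rr(or, rate) - 1,
    outcome = outcome, scope = scope,
    scope_value = scope_value %||% "pooled",
    window_months = window_months, model_ic = ic,
    n = nrow(d), n_clusters = length(unique(d$city_id)),
    method = method, converged = conv, covariate_coefs = coefs,
    formula = fml), class = "assoc_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.assoc_fit <- function(x, ...) {
  cat(sprintf("<assoc_fit: %s anemia, scope %s, %d-month window, n = %d>\n",
              x$outcome, x$scope_value, x$window_months, x$n))
  cat(sprintf("  OR/degC %.3f (95%% CI %.3f-%.3f)  RR %.4f  rate %.4f  ERC %.4f\n",
              x$or_per_degc, x$or_ci[1], x$or_ci[2], x$rr_per_degc, x$rate,
              x$erc))
  invisible(x)
}

#' Per-country association fits for the burden projection
#'
#' Fits the association model country by country and returns the tidy table
#' of country odds ratios, prevalences (`rate_c`), risk ratios and excess
#' risk coefficients consumed by the burden module. A pooled log-odds
#' estimate can be substituted for countries whose own fit fails.
#'
#' @inheritParams fit_association
#' @param ... passed to [fit_association()].
#' @return A tibble, one row per country: `country_code`, `beta`, `se`,
#'   `or`, `rate`, `rr`, `erc`, `n`.
#' @export
fit_country_associations <- function(records, exposures,
                                     country_covariates = NULL, ...) {
  purrr::map_dfr(sort(unique(records$country_code)), function(cc) {
    f <- fit_association(records, exposures, country_covariates,
                         scope = "country", scope_value = cc, ...)
    tibble::tibble(country_code = cc, beta = f$beta_temp, se = f$se_beta,
                   or = f$or_per_degc, rate = f$rate, rr = f$rr_per_degc,
                   erc = f$erc, n = f$n)
  })
}

#' Exposure-response curve and linearity test
#'
#' Depicts the shape of the annual-temperature / anemia relationship with a
#' natural cubic spline (3 degrees of freedom by default) in the covariate-
#' adjusted logistic model, and tests departure from linearity with an
#' ANOVA F test between the nested linear and spline fits (quasibinomial
#' working family so the F reference distribution applies). Fixed-effects
#' fits are used for the curve comparison.
#'
#' @inheritParams fit_association
#' @param df spline degrees of freedom.
#' @param n_grid number of temperature grid points for the returned curve.
#' @return An `er_curve` object: tibble `curve` (temperature, centered
#'   log-odds and 95% CI), `p_linearity`, and the two model AICs.
#' @export
er_curve <- function(records, exposures, country_covariates = NULL,
                     window_months = 12, covariates = assoc_covariates(),
                     df = 3, n_grid = 50) {
  d <- assoc_model_frame(records, exposures, country_covariates,
                         window_months, "any", covariates)
  covs <- setdiff(intersect(covariates, names(d)),
                  c("outcome", "mean_temperature"))
  rhs <- paste(covs, collapse = " + ")
  f_lin <- glm(as.formula(paste("outcome ~ mean_temperature +", rhs)),
               data = d, family = stats::quasibinomial())
  f_spl <- glm(as.formula(
    paste("outcome ~ splines::ns(mean_temperature, df = ", df, ") +", rhs)),
    data = d, family = stats::quasibinomial())
  an <- anova(f_lin, f_spl, test = "F")
  p_lin <- an[["Pr(>F)"]][2]
  tgrid <- seq(min(d$mean_temperature), max(d$mean_temperature),
               length.out = n_grid)
  B <- splines::ns(d$mean_temperature, df = df)
  Bg <- predict(B, tgrid)
  sel <- grep("^splines::ns", names(coef(f_spl)))
  cb <- coef(f_spl)[sel]
  V <- vcov(f_spl)[sel, sel, drop = FALSE]
  ref <- Bg[which.min(abs(tgrid - median(d$mean_temperature))), ]
  Bc <- sweep(Bg, 2, ref)   # curve centered at the median temperature
  eta <- as.vector(Bc %*% cb)
  se <- sqrt(rowSums((Bc %*% V) * Bc))
  curve <- tibble::tibble(temperature = tgrid, log_odds = eta,
                          lo = eta - qnorm(0.975) * se,
                          hi = eta + qnorm(0.975) * se)
  structure(list(curve = curve, p_linearity = p_lin, df = df, n = nrow(d)),
            class = "er_curve")
}

#' @export
print.er_curve <- function(x, ...) {
  cat(sprintf("<er_curve: ns(%d df), n = %d, linearity F-test p = %.3g>\n",
              x$df, x$n, x$p_linearity))
  invisible(x)
}
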