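#' Difference-of-coefficients mediation of the temperature effect
#'
#' Decomposes the annual-temperature / anemia association through one binary
#' mediator — childhood malnutrition (Kaup index, i.e. child BMI, below 15
#' kg/m2) or malaria infection (positive rapid diagnostic test). The total
#' effect (TE) is the temperature log-odds coefficient of the main model;
#' the direct effect (DE) is the same coefficient after additionally
#' adjusting for the mediator; the indirect effect is `IE = TE - DE` and the
#' percentage mediated is `100 * IE / TE`. Both fits use the identical
#' complete-case row set, so adjusting for the mediator never changes `n`.
#' Empirical 95% CIs come from a seeded percentile bootstrap (clusters
#' resampled with replacement by default, respecting the survey design;
#' individual-level resampling is available).
#'
#' Because the malnutrition mediator is a deterministic threshold of BMI,
#' the continuous BMI covariate of the main association model is excluded
#' from both mediation fits — conditioning on exact BMI would block the
#' malnutrition pathway by construction. The decomposition is the usual
#' difference-of-coefficients approximation on the log-odds scale; odds-
#' ratio non-collapsibility makes it exact only for modest effects.
#'
#' @param records child records (see [generate_survey()]).
#' @param exposures per-cluster exposure table from [cluster_exposures()].
#' @param mediator `"malnutrition"` or `"malaria"`.
#' @param country_covariates optional country-level covariate table.
#' @param n_boot number of bootstrap resamples (the reference analysis uses
#'   1,000).
#' @param seed integer seed for the bootstrap.
#' @param resample `"cluster"` (default) or `"individual"`.
#' @param window_months exposure window for the temperature term.
#' @param covariates fixed covariates of the main model; BMI is removed
#'   internally (see Details).
#' @return A `mediation_result` object; `tidy()` returns the effect table,
#'   the `draws` element holds the bootstrap replicates.
#' @export
run_mediation <- function(records, exposures,
                          mediator = c("malnutrition", "malaria"),
                          country_covariates = NULL,
                          n_boot = 1000, seed = 1L,
                          resample = c("cluster", "individual"),
                          window_months = 12,
                          covariates = assoc_covariates()) {
  mediator <- match.arg(mediator)
  resample <- match.arg(resample)
  covariates <- setdiff(covariates, "bmi")
  records <- tibble::as_tibble(records)
  records$.row_id <- seq_len(nrow(records))
  d <- assoc_model_frame(records, exposures, country_covariates,
                         window_months, "any", c(covariates, ".row_id"))
  m_all <- if (mediator == "malnutrition") {
    as.integer(records$bmi < 15)
  } else {
    as.integer(records$malaria_rdt == "positive")
  }
  d$mediator <- m_all[d$.row_id]
  d <- d[!is.na(d$mediator), ]

  covs <- setdiff(intersect(covariates, names(d)),
                  c("outcome", "mean_temperature", ".row_id", "mediator"))
  # city fixed effects stand in for the main model's city random intercept:
  # they absorb city-level heterogeneity in every bootstrap refit
  if ("city_id" %in% names(d) && length(unique(d$city_id)) > 1L) {
    d$city_id <- factor(d$city_id)
    covs <- c(covs, "city_id")
  }
  fml <- as.formula(paste("outcome ~ mean_temperature +",
                          paste(covs, collapse = " + ")))
  X <- model.matrix(fml, data = d)
  # drop aliased columns once (country-level covariates vs city dummies)
  qx <- qr(X)
  if (qx$rank < ncol(X)) X <- X[, sort(qx$pivot[seq_len(qx$rank)]), drop = FALSE]
  y <- d$outcome
  # standardize once; fitted coefficients are rescaled back below
  scl <- sqrt(colMeans(X^2)); scl[scl < 1e-12] <- 1
  X <- sweep(X, 2, scl, "/")
  Xm <- cbind(X, mediator = d$mediator)
  k <- which(colnames(X) == "mean_temperature")
  sT <- scl[[k]]

  st_te <- fast_logit_fit(X, y, prescaled = TRUE)
  st_de <- fast_logit_fit(Xm, y, start = c(st_te, 0), prescaled = TRUE)
  te <- st_te[k] / sT
  de <- st_de[k] / sT
  ie <- te - de
  pct <- if (abs(te) < 1e-6) NA_real_ else 100 * ie / te

  set.seed(seed)
  if (resample == "cluster") {
    cl <- split(seq_len(nrow(d)), d$cluster_id)
    draw_rows <- function() unlist(cl[sample.int(length(cl), replace = TRUE)],
                                   use.names = FALSE)
  } else {
    draw_rows <- function() sample.int(nrow(d), replace = TRUE)
  }
  draws <- purrr::map_dfr(seq_len(n_boot), function(b) {
    rows <- draw_rows()
    te_b <- fast_logit_fit(X[rows, , drop = FALSE], y[rows], start = st_te,
                           prescaled = TRUE)[k] / sT
    de_b <- fast_logit_fit(Xm[rows, , drop = FALSE], y[rows], start = st_de,
                           prescaled = TRUE)[k] / sT
    tibble::tibble(draw = b, te = te_b, de = de_b, ie = te_b - de_b,
                   pct_mediated = if (abs(te_b) < 1e-6) NA_real_
                                  else 100 * (te_b - de_b) / te_b)
  })
  ci_ie <- unname(quantile(draws$ie, c(0.025, 0.975), na.rm = TRUE))
  ci_pct <- unname(quantile(draws$pct_mediated, c(0.025, 0.975), na.rm = TRUE))
  structure(list(mediator = mediator, te = unname(te), de = unname(de),
                 ie = unname(ie), pct_mediated = unname(pct),
                 ci_ie = ci_ie, ci_pct = ci_pct, n_boot = n_boot,
                 n = nrow(d), resample = resample, seed = seed,
                 draws = draws),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result: %s, n = %d, %d bootstrap draws (%s resampling)>\n",
              x$mediator, x$n, x$n_boot, x$resample))
  cat(sprintf("  TE %.4f  DE %.4f  IE %.4f (95%% eCI %.4f, %.4f)\n",
              x$te, x$de, x$ie, x$ci_ie[1], x$ci_ie[2]))
  if (is.na(x$pct_mediated)) {
    cat("  %% mediated undefined (total effect ~ 0)\n")
  } else {
    cat(sprintf("  %%mediated %.2f (95%% eCI %.2f, %.2f)\n",
                x$pct_mediated, x$ci_pct[1], x$ci_pct[2]))
  }
  invisible(x)
}

#' Write a mediation result as JSON plus bootstrap draws CSV
#'
#' @param result a `mediation_result`.
#' @param dir output directory; writes `mediation_<mediator>.json` and
#'   `mediation_<mediator>_draws.csv`.
#' @return The directory, invisibly.
#' @export
write_mediation_json <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- result[c("mediator", "te", "de", "ie", "pct_mediated", "ci_ie",
                  "ci_pct", "n_boot", "n", "resample", "seed")]
  jsonlite::write_json(out, file.path(dir, paste0("mediation_", result$mediator,
                                                  ".json")),
                       auto_unbox = TRUE, digits = NA)
  write.csv(result$draws,
            file.path(dir, paste0("mediation_", result$mediator, "_draws.csv")),
            row.names = FALSE)
  invisible(dir)
}
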