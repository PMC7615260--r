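#' Tidy an association fit
#'
#' @param x an `assoc_fit`.
#' @param ... unused.
#' @return A one-row tibble with the temperature effect on every reported
#'   scale: log-odds, OR and RR per +1 degC with 95% CIs, the scope
#'   prevalence and the excess risk coefficient.
#' @export
tidy.assoc_fit <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome, scope = x$scope, scope_value = x$scope_value,
    window_months = x$window_months,
    beta_temp = x$beta_temp, se_beta = x$se_beta,
    or_per_degc = x$or_per_degc, or_low = x$or_ci[1], or_high = x$or_ci[2],
    rr_per_degc = x$rr_per_degc, rr_low = x$rr_ci[1], rr_high = x$rr_ci[2],
    rate = x$rate, erc = x$erc)
}

#' @rdname tidy.assoc_fit
#' @export
glance.assoc_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_clusters = x$n_clusters, method = x$method,
                 converged = x$converged, model_ic = x$model_ic,
                 window_months = x$window_months)
}

#' Tidy a mediation result
#'
#' @param x a `mediation_result`.
#' @param ... unused.
#' @return A one-row tibble with TE, DE, IE (log-odds per degC), the
#'   percentage mediated and bootstrap 95% eCIs.
#' @export
tidy.mediation_result <- function(x, ...) {
  tibble::tibble(
    mediator = x$mediator, te = x$te, de = x$de, ie = x$ie,
    ie_low = x$ci_ie[1], ie_high = x$ci_ie[2],
    pct_mediated = x$pct_mediated,
    pct_low = x$ci_pct[1], pct_high = x$ci_pct[2])
}

#' @rdname tidy.mediation_result
#' @export
glance.mediation_result <- function(x, ...) {
  tibble::tibble(n = x$n, n_boot = x$n_boot, resample = x$resample,
                 seed = x$seed)
}

#' Tidy an exposure-response curve
#'
#' @param x an `er_curve`.
#' @param ... unused.
#' @return The curve tibble: temperature, centered log-odds and 95% CI.
#' @export
tidy.er_curve <- function(x, ...) x$curve

#' @rdname tidy.er_curve
#' @export
glance.er_curve <- function(x, ...) {
  tibble::tibble(p_linearity = x$p_linearity, df = x$df, n = x$n)
}

#' Tidy a burden projection
#'
#' @param x a `burden_result`.
#' @param ... unused.
#' @return The burden table as a plain tibble.
#' @export
tidy.burden_result <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}
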