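#' Published country-level survey summary
#'
#' Loads the packaged country-level summary of the multi-country under-5
#' survey sample (sample sizes, percentages of the pooled sample, anemia
#' prevalence and annual-temperature summaries per country, region and
#' overall). Used as the arithmetic ground truth for internal-consistency
#' checks of descriptive aggregation.
#'
#' @param path CSV path; defaults to the packaged file.
#' @return A tibble with columns `level` (`country`/`region`/`total`),
#'   `region`, `name`, `n`, `percentage`, `anemia_prevalence`, `temp_mean`,
#'   `temp_sd`, `temp_min`, `temp_max`.
#' @export
read_country_summary <- function(path = NULL) {
  path <- path %||% system.file("extdata", "ssa_country_summary.csv",
                                package = "climanemia", mustWork = TRUE)
  tibble::as_tibble(read.csv(path, check.names = FALSE))
}

#' Recompute regional and total rows from country rows
#'
#' Aggregates the country rows of a summary table the way a descriptive
#' table is built from microdata: regional and total `n` are sums,
#' percentages are `n` over the grand total times 100, prevalence is the
#' `n`-weighted mean of country prevalences, and temperature min/max are the
#' extremes of the country values. Results are rounded to 2 decimals
#' (percentages, prevalence) and 1 decimal (temperature) to match printed
#' precision.
#'
#' @param summary a summary tibble from [read_country_summary()] (only its
#'   `country` rows are used).
#' @return A tibble of recomputed `region` rows plus a `total` row.
#' @export
summarise_country_table <- function(summary) {
  cc <- summary[summary$level == "country", ]
  grand_n <- sum(cc$n)
  reg <- dplyr::summarise(
    dplyr::group_by(cc, .data$region),
    anemia_prevalence = round(sum(.data$n * .data$anemia_prevalence) /
                                sum(.data$n), 2),
    percentage = round(100 * sum(.data$n) / grand_n, 2),
    n = sum(.data$n),
    temp_min = min(.data$temp_min),
    temp_max = max(.data$temp_max),
    .groups = "drop")
  reg$level <- "region"; reg$name <- reg$region
  tot <- tibble::tibble(
    level = "total", region = "Total", name = "Total", n = grand_n,
    percentage = 100,
    anemia_prevalence = round(sum(cc$n * cc$anemia_prevalence) / grand_n, 2),
    temp_min = min(cc$temp_min), temp_max = max(cc$temp_max))
  dplyr::bind_rows(reg[, names(tot)], tot)
}

#' Internal-consistency check of a published summary table
#'
#' Compares every recomputable aggregate of the summary table (regional and
#' total sample sizes, sample percentages, weighted anemia prevalences and
#' temperature extremes, plus each country's percentage of the pooled
#' sample) against the printed values, after rounding to the printed
#' precision.
#'
#' @param summary a summary tibble from [read_country_summary()].
#' @return A tibble with one row per checked quantity: `name`, `quantity`,
#'   `printed`, `recomputed`, `abs_diff`, `consistent`.
#' @export
check_summary_consistency <- function(summary) {
  rec <- summarise_country_table(summary)
  printed <- summary[summary$level != "country",
                     c("name", "n", "percentage", "anemia_prevalence",
                       "temp_min", "temp_max")]
  long <- function(df, src) {
    tidyr::pivot_longer(df, c("n", "percentage", "anemia_prevalence",
                              "temp_min", "temp_max"),
                        names_to = "quantity", values_to = src)
  }
  chk <- dplyr::inner_join(long(printed, "printed"),
                           long(rec[, names(printed)], "recomputed"),
                           by = c("name", "quantity"))
  cc <- summary[summary$level == "country", ]
  cpct <- tibble::tibble(
    name = cc$name, quantity = "percentage", printed = cc$percentage,
    recomputed = round(100 * cc$n / sum(cc$n), 2))
  chk <- dplyr::bind_rows(chk, cpct)
  chk$abs_diff <- abs(chk$printed - chk$recomputed)
  chk$consistent <- chk$abs_diff < 1e-9
  chk
}
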