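# Shared small synthetic worlds, built once per test run.

small_cfg <- function(...) {
  args <- list(seed = 101, n_countries = 2, clusters_per_country = 12,
               children_per_cluster = 15, n_gcms = 3, grid_resolution = 1.0,
               years = c(2000L, 2030L), survey_years = c(2012L, 2014L),
               baseline_window = c(2000L, 2014L))
  do.call(synth_config, utils::modifyList(args, list(...)))
}

# a small complete world reused across files (read-only!)
cached_world <- local({
  w <- NULL
  function() {
    if (is.null(w)) w <<- suppressMessages(generate_world(small_cfg()))
    w
  }
})

# a moderate-size survey for fitting tests (read-only!)
cached_fit_world <- local({
  w <- NULL
  function() {
    if (is.null(w)) {
      cfg <- synth_config(seed = 202, n_countries = 4,
                          clusters_per_country = 50, children_per_cluster = 40,
                          years = c(2000L, 2020L), survey_years = c(2012L, 2016L))
      cl <- generate_climate(cfg)
      sv <- suppressMessages(generate_survey(cfg, cl))
      ex <- cluster_exposures(cl, sv$sites)
      w <<- list(cfg = cfg, climate = cl, survey = sv, exposures = ex)
    }
    w
  }
})

# tiny analytic grid helpers for climate-operation oracles
toy_grid <- function(vals, lat = NULL, lon = NULL, time = as.Date("2000-01-01"),
                     variable = "temperature") {
  if (is.matrix(vals)) vals <- array(vals, dim = c(dim(vals), length(time)))
  if (is.null(lat)) lat <- seq_len(dim(vals)[1])
  if (is.null(lon)) lon <- seq_len(dim(vals)[2])
  grid_field(lat, lon, time, vals, variable = variable)
}
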