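#' Generate a complete synthetic world
#'
#' Convenience wrapper tying the generators together with a single seed:
#' climate archive, survey microdata (linked to the reference grid through
#' the exposure module), city boundaries and population grids.
#'
#' @param config a [synth_config()].
#' @return A `synth_world` list: `config`, `climate`, `survey`,
#'   `boundaries`, `population`.
#' @export
generate_world <- function(config) {
  climate <- generate_climate(config)
  survey <- generate_survey(config, climate)
  population <- generate_population(config)
  structure(list(config = config, climate = climate, survey = survey,
                 boundaries = survey$boundaries, population = population),
            class = "synth_world")
}

#' @export
print.synth_world <- function(x, ...) {
  cat("<synth_world>\n")
  print(x$config)
  invisible(x)
}
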