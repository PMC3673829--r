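#' The Syria 2003-2022 projection preset
#'
#' Loads the configuration shipped with the package for projecting type 2
#' diabetes prevalence among Syrian adults aged 25 and over from 2003 to
#' 2022: per-band population denominators reconstructed from the published
#' report cells, the 2003 baseline prevalence surface, an all-cause
#' mortality schedule, sex-level incidence, literature relative risks, the
#' obesity/smoking trend rules and the 10-year prevention-program scenario.
#'
#' @return An `impact_config` with the scenario attached, plus attributes
#'   `pop_20_24` (the 20-24 population trajectory used by
#'   [idf_comparable()]) and `report` (the published report cells).
#' @export
#' @examples
#' cfg <- syria_preset()
#' proj <- run_projection(cfg)
#' proj
syria_preset <- function() {
  path <- system.file("extdata", "syria_config.yaml", package = "impactdm")
  cfg <- read_config_yaml(path)
  p2024 <- readr::read_csv(
    system.file("extdata", "syria_pop_20_24.csv", package = "impactdm"),
    col_types = readr::cols(
      year = readr::col_integer(), sex = readr::col_character(),
      count = readr::col_double()
    )
  )
  attr(cfg, "pop_20_24") <- p2024
  attr(cfg, "report") <- readr::read_csv(
    system.file("extdata", "syria_table1.csv", package = "impactdm"),
    col_types = readr::cols()
  )
  cfg
}

#' Interpolated 20-24 population trajectory for the Syria preset
#'
#' Expands the preset's sparse 20-24 anchors to every horizon year by
#' per-stratum geometric interpolation (the same convention as the model
#' bands).
#'
#' @param cfg A config from [syria_preset()].
#' @return A tibble `year`, `sex`, `count` covering the full horizon.
#' @export
syria_pop_20_24 <- function(cfg = syria_preset()) {
  anchors <- attr(cfg, "pop_20_24")
  anchors$age_lower <- 20L
  anchors$age_upper <- 25L
  traj <- build_population_trajectory(
    anchors, cfg$horizon[1]:cfg$horizon[2]
  )
  traj[c("year", "sex", "count")]
}
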