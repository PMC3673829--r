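#' Assemble a projection configuration
#'
#' Bundles every input the Markov engine needs. All tabular arguments are
#' data frames keyed by (`sex`, `age_lower`, `age_upper`) over the same
#' stratum set.
#'
#' @param horizon Length-2 integer vector `c(start_year, end_year)`.
#' @param population Population anchors (`year`, `sex`, `age_lower`,
#'   `age_upper`, `count`); in anchored mode they must span the horizon.
#' @param baseline_prevalence Diabetes prevalence at the first horizon year
#'   (`prevalence` as a proportion). If built from self-reported survey
#'   data, apply [adjust_underdiagnosis()] beforehand.
#' @param mortality All-cause mortality (`rate`, per person-year).
#' @param incidence One of: a data frame with per-stratum `incidence`
#'   hazards; `list(type = "uniform_by_sex", per_100k = c(M = ..., F =
#'   ...))`; or `list(type = "estimate")` to back-calculate from the
#'   baseline prevalence curve via [estimate_incidence_from_prevalence()].
#' @param relative_risks `list(mort_dm=, dm_obese=, dm_smoker=, joint =
#'   "multiplicative"|"max")`, all ratios > 0.
#' @param risk_factors Exposure baselines and trends (`obesity`, `smoking`
#'   proportions; `obesity_trend_pp`, `smoking_trend_pp` in percentage
#'   points per year).
#' @param obesity_cap Ceiling on obesity prevalence (default 0.80).
#' @param rate_type `"probability"` (inputs are annual probabilities, used
#'   directly) or `"hazard"` (converted via `1 - exp(-h)`).
#' @param demography_mode `"anchored"` (living band populations follow the
#'   interpolated anchor trajectory; entrants are the per-sex top-up) or
#'   `"closed"` (population evolves by deaths/aging only).
#' @param closed_entrants Entrants per sex and year in closed mode.
#' @param scenario Optional default [scenario_spec()] stored with the
#'   config (runs still take an explicit `scenario` argument).
#' @return An `impact_config` list.
#' @export
projection_config <- function(horizon, population, baseline_prevalence,
                              mortality, incidence, relative_risks,
                              risk_factors, obesity_cap = 0.80,
                              rate_type = c("probability", "hazard"),
                              demography_mode = c("anchored", "closed"),
                              closed_entrants = c(M = 0, F = 0),
                              scenario = NULL) {
  structure(
    list(
      horizon = as.integer(horizon),
      population = population,
      baseline_prevalence = baseline_prevalence,
      mortality = mortality,
      incidence = incidence,
      relative_risks = relative_risks,
      risk_factors = risk_factors,
      obesity_cap = obesity_cap,
      rate_type = match.arg(rate_type),
      demography_mode = match.arg(demography_mode),
      closed_entrants = closed_entrants,
      scenario = scenario
    ),
    class = "impact_config"
  )
}

#' Validate a projection configuration
#'
#' Checks completeness and ranges, reporting every problem at once.
#'
#' @param config An `impact_config`.
#' @return `config`, invisibly; errors with the full problem list otherwise.
#' @export
validate_config <- function(config) {
  problems <- character()
  need <- function(cond, msg) {
    if (!isTRUE(cond)) problems <<- c(problems, msg)
  }
  need(
    is.numeric(config$horizon) && length(config$horizon) == 2 &&
      config$horizon[1] < config$horizon[2],
    "horizon must be c(start, end) with start < end"
  )
  for (tab in c("population", "baseline_prevalence", "mortality",
                "risk_factors")) {
    need(is.data.frame(config[[tab]]), paste(tab, "must be a data frame"))
  }
  if (is.data.frame(config$baseline_prevalence)) {
    need(
      "prevalence" %in% names(config$baseline_prevalence) &&
        all(config$baseline_prevalence$prevalence >= 0 &
          config$baseline_prevalence$prevalence <= 1),
      "baseline_prevalence$prevalence must lie in [0, 1]"
    )
  }
  if (is.data.frame(config$mortality)) {
    need(
      "rate" %in% names(config$mortality) && all(config$mortality$rate >= 0),
      "mortality$rate must be >= 0"
    )
  }
  rr <- config$relative_risks
  need(
    is.list(rr) && all(c("mort_dm", "dm_obese", "dm_smoker") %in% names(rr)),
    "relative_risks must name mort_dm, dm_obese, dm_smoker"
  )
  if (is.list(rr) &&
    all(c("mort_dm", "dm_obese", "dm_smoker") %in% names(rr))) {
    need(
      all(unlist(rr[c("mort_dm", "dm_obese", "dm_smoker")]) > 0),
      "all relative risks must be > 0"
    )
  }
  if (is.data.frame(config$risk_factors)) {
    rk <- config$risk_factors
    need(
      all(c("obesity", "smoking", "obesity_trend_pp", "smoking_trend_pp")
        %in% names(rk)),
      "risk_factors needs obesity, smoking, obesity_trend_pp, smoking_trend_pp"
    )
    if (all(c("obesity", "smoking") %in% names(rk))) {
      need(
        all(rk$obesity >= 0 & rk$obesity <= 1 &
          rk$smoking >= 0 & rk$smoking <= 1),
        "exposure prevalences must lie in [0, 1]"
      )
    }
  }
  need(
    is.numeric(config$obesity_cap) && config$obesity_cap > 0 &&
      config$obesity_cap <= 1,
    "obesity_cap must lie in (0, 1]"
  )
  need(
    is.data.frame(config$incidence) ||
      (is.list(config$incidence) &&
        isTRUE(config$incidence$type %in% c("uniform_by_sex", "estimate"))),
    "incidence must be a table, uniform_by_sex spec, or 'estimate'"
  )
  if (length(problems)) {
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "),
      call. = FALSE
    )
  }
  invisible(config)
}

#' Adjust self-reported prevalence for under-diagnosis
#'
#' Chronic-disease surveys based on self report miss undiagnosed cases;
#' a standard correction multiplies the self-reported prevalence by a
#' factor (1.5 by default), capped at 1. Apply once, at data preparation.
#'
#' @param prevalence Self-reported prevalence (proportion), vectorised.
#' @param factor Under-diagnosis multiplier (default 1.5).
#' @return Adjusted prevalence, capped at 1.
#' @export
adjust_underdiagnosis <- function(prevalence, factor = 1.5) {
  if (any(prevalence < 0 | prevalence > 1)) {
    stop("prevalence must lie in [0, 1]", call. = FALSE)
  }
  pmin(1, prevalence * factor)
}

#' Read a master configuration from YAML
#'
#' Reads the nested key-value layout shipped as
#' `system.file("extdata", "syria_config.yaml", package = "impactdm")`:
#' sections `horizon`, `demography`, `rates`, `relative_risks`,
#' `risk_factors`, `scenario`. Referenced CSV paths are resolved relative
#' to the YAML file.
#'
#' @param path Path to the YAML file.
#' @return An `impact_config` (with any `scenario` section attached).
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  dir <- dirname(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(dir, p)

  report <- NULL
  if (!is.null(raw$demography$report_csv)) {
    report <- readr::read_csv(resolve(raw$demography$report_csv),
      col_types = readr::cols()
    )
    pop <- reconstruct_denominators(report)
  } else if (!is.null(raw$demography$population_csv)) {
    pop <- read_population_csv(resolve(raw$demography$population_csv))
  } else {
    stop("demography section needs report_csv or population_csv",
      call. = FALSE
    )
  }
  mortality <- readr::read_csv(resolve(raw$rates$mortality_csv),
    col_types = readr::cols()
  )
  bands <- age_bands_core()

  prev <- if (!is.null(report)) {
    first_year <- raw$horizon$start
    sub <- report[report$year == first_year, ]
    pb <- parse_age_band(sub$band)
    tibble::tibble(
      sex = sub$sex, age_lower = pb$age_lower, age_upper = pb$age_upper,
      prevalence = sub$prevalence_pct / 100
    )
  } else {
    readr::read_csv(resolve(raw$rates$prevalence_csv),
      col_types = readr::cols()
    )
  }

  inc <- raw$rates$incidence
  if (is.list(inc) && identical(inc$type, "uniform_by_sex")) {
    inc <- list(
      type = "uniform_by_sex",
      per_100k = c(M = inc$per_100k$M, F = inc$per_100k$F)
    )
  }

  rf <- raw$risk_factors
  risk <- tidyr::crossing(bands[c("age_lower", "age_upper")],
    sex = c("M", "F")
  )
  risk$obesity <- unlist(rf$obesity$baseline[risk$sex])
  risk$smoking <- unlist(rf$smoking$baseline[risk$sex])
  risk$obesity_trend_pp <- ifelse(
    risk$age_lower == min(risk$age_lower),
    rf$obesity$trend_pp_young, rf$obesity$trend_pp_per_year
  )
  risk$smoking_trend_pp <- rf$smoking$trend_pp_per_year

  scen <- NULL
  if (!is.null(raw$scenario)) {
    scen <- scenario_spec(
      start_year = raw$scenario$start_year,
      duration = raw$scenario$duration,
      obesity_reduction = raw$scenario$obesity_reduction,
      smoking_reduction = raw$scenario$smoking_reduction,
      target_fraction_healthy = raw$scenario$target_fractions$healthy,
      target_fraction_obese = raw$scenario$target_fractions$obese,
      target_fraction_smoker = raw$scenario$target_fractions$smoker,
      reading = raw$scenario$reading %||% "population_wide"
    )
  }

  projection_config(
    horizon = c(raw$horizon$start, raw$horizon$end),
    population = pop,
    baseline_prevalence = prev,
    mortality = mortality,
    incidence = inc,
    relative_risks = list(
      mort_dm = raw$relative_risks$mort_dm,
      dm_obese = raw$relative_risks$dm_obese,
      dm_smoker = raw$relative_risks$dm_smoker,
      joint = raw$relative_risks$joint %||% "multiplicative"
    ),
    risk_factors = risk,
    obesity_cap = rf$obesity$cap %||% 0.80,
    rate_type = raw$rates$rate_type %||% "probability",
    demography_mode = raw$demography$mode %||% "anchored",
    scenario = scen
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
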