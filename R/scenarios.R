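#' Define a prevention-program scenario
#'
#' A counterfactual intervention that lowers exposure (obesity, smoking)
#' prevalences relative to their baseline trend, phased in linearly over a
#' fixed duration and persisting at full strength afterwards. It acts only
#' on the non-diabetic exposure pools; existing diabetes cases are never
#' touched.
#'
#' Two operational readings are supported:
#' * `"population_wide"` (default): each exposure prevalence is multiplied
#'   by `1 - reduction * phase`, i.e. the stated reduction applies to the
#'   whole exposure pool.
#' * `"targeted"`: only the targeted fraction of each pool achieves the
#'   reduction, giving the multiplier
#'   `1 - target_fraction * reduction * phase`.
#'
#' The targeted fraction of the healthy pool is stored for completeness but
#' has no effect: healthy individuals carry no exposure to reduce.
#'
#' @param start_year First calendar year of the program.
#' @param duration Phase-in duration in years (>= 1).
#' @param obesity_reduction,smoking_reduction Relative reductions achieved
#'   by the end of the phase-in, proportions in \[0, 1\].
#' @param target_fraction_healthy,target_fraction_obese,target_fraction_smoker
#'   Fractions of each pool targeted by the program, in \[0, 1\].
#' @param reading Operational reading, see Details.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(start_year, duration,
                          obesity_reduction, smoking_reduction,
                          target_fraction_healthy = 0,
                          target_fraction_obese = 1,
                          target_fraction_smoker = 1,
                          reading = c("population_wide", "targeted")) {
  reading <- match.arg(reading)
  stopifnot(
    duration >= 1,
    obesity_reduction >= 0, obesity_reduction <= 1,
    smoking_reduction >= 0, smoking_reduction <= 1,
    target_fraction_healthy >= 0, target_fraction_healthy <= 1,
    target_fraction_obese >= 0, target_fraction_obese <= 1,
    target_fraction_smoker >= 0, target_fraction_smoker <= 1
  )
  structure(
    list(
      start_year = as.integer(start_year), duration = as.integer(duration),
      obesity_reduction = obesity_reduction,
      smoking_reduction = smoking_reduction,
      target_fraction_healthy = target_fraction_healthy,
      target_fraction_obese = target_fraction_obese,
      target_fraction_smoker = target_fraction_smoker,
      reading = reading, phase_in = "linear"
    ),
    class = "scenario_spec"
  )
}

#' Linear phase-in fraction of a scenario at a calendar year
#'
#' `0` before the start year, `(year - start + 1) / duration` during the
#' phase-in window, `1` afterwards.
#'
#' @param spec A [scenario_spec()].
#' @param year Calendar year.
#' @return Phase fraction in \[0, 1\].
#' @export
scenario_phase <- function(spec, year) {
  if (year < spec$start_year) {
    return(0)
  }
  min(1, (year - spec$start_year + 1) / spec$duration)
}

#' Intervention multiplier on an exposure prevalence
#'
#' @param reduction Relative reduction at full phase-in.
#' @param phase Phase fraction from [scenario_phase()].
#' @param target_fraction Targeted fraction of the pool (ignored under the
#'   population-wide reading).
#' @param reading `"population_wide"` or `"targeted"`.
#' @return Multiplier in \[0, 1\].
#' @export
#' @examples
#' # half-way through the phase-in, 25% reduction in 40% of the pool:
#' intervention_multiplier(0.25, 0.5, 0.4, "targeted") # pool-level 0.95
#' # the targeted pool itself is at 1 - 0.25 * 0.5 = 0.875
intervention_multiplier <- function(reduction, phase, target_fraction = 1,
                                    reading = "population_wide") {
  if (identical(reading, "targeted")) {
    1 - target_fraction * reduction * phase
  } else {
    1 - reduction * phase
  }
}

#' Apply an intervention to a trend-updated risk-factor table
#'
#' Multiplies the obesity and smoking prevalences that the baseline trend
#' would produce in `year` by the scenario's phased multipliers.
#'
#' @param risk Risk-factor table for `year` (columns `obesity`, `smoking`).
#' @param spec A [scenario_spec()].
#' @param year Calendar year the table refers to.
#' @return The modified risk table.
#' @export
apply_intervention <- function(risk, spec, year) {
  phase <- scenario_phase(spec, year)
  if (phase == 0) {
    return(risk)
  }
  risk$obesity <- risk$obesity * intervention_multiplier(
    spec$obesity_reduction, phase, spec$target_fraction_obese, spec$reading
  )
  risk$smoking <- risk$smoking * intervention_multiplier(
    spec$smoking_reduction, phase, spec$target_fraction_smoker, spec$reading
  )
  risk
}

#' Run a projection under an intervention scenario
#'
#' Convenience wrapper: re-runs [run_projection()] with the scenario
#' applied to the exposure trajectories.
#'
#' @inheritParams run_projection
#' @param spec A [scenario_spec()]; defaults to the one stored in the
#'   config.
#' @return An `impact_projection`.
#' @export
run_scenario <- function(config, spec = config$scenario) {
  if (is.null(spec)) stop("no scenario specified", call. = FALSE)
  if (spec$start_year < config$horizon[1] ||
    spec$start_year > config$horizon[2]) {
    stop("scenario start ", spec$start_year, " lies outside the horizon",
      call. = FALSE
    )
  }
  run_projection(config, scenario = spec)
}

#' Compare a baseline and an intervention projection
#'
#' @param baseline,intervention `impact_projection` objects sharing horizon
#'   and strata.
#' @param years Years of interest (default: the full shared horizon).
#' @return A tibble per year: overall prevalence under both runs (percent),
#'   `pp_difference` (percentage points), `relative_reduction_pct`, and
#'   `cases_averted` (persons).
#' @export
compare_scenarios <- function(baseline, intervention,
                              years = baseline$years) {
  if (!identical(baseline$years, intervention$years) ||
    !identical(baseline$strata, intervention$strata)) {
    stop("projections do not share horizon and strata", call. = FALSE)
  }
  b <- baseline$totals[baseline$totals$sex == "all", ]
  i <- intervention$totals[intervention$totals$sex == "all", ]
  b <- b[b$year %in% years, ]
  i <- i[i$year %in% years, ]
  tibble::tibble(
    year = b$year,
    prevalence_baseline = 100 * b$prevalence,
    prevalence_intervention = 100 * i$prevalence,
    pp_difference = 100 * (b$prevalence - i$prevalence),
    relative_reduction_pct = 100 * (b$prevalence - i$prevalence) /
      b$prevalence,
    cases_averted = b$cases - i$cases
  )
}
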