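#' Specify a synthetic country
#'
#' Defines a small synthetic population with known, constant ground-truth
#' hazards per stratum, for which the illness-death dynamics have a closed
#' form. Generated bundles exercise every pipeline stage (demography
#' interpolation, rate estimation, projection) with recoverable truth.
#'
#' @param seed Integer seed controlling any stochastic perturbation derived
#'   from the bundle (generation itself is deterministic).
#' @param horizon Length-2 vector `c(start_year, end_year)`.
#' @param bands Band table as from [age_bands_core()]; defaults to the
#'   first three core bands to keep fixtures small.
#' @param base_pop Baseline population per stratum (single number recycled,
#'   or vector of length strata).
#' @param growth Annual population growth rate per stratum (proportion).
#' @param incidence,m0,excess True constant hazards per person-year
#'   (recycled per stratum).
#' @param obesity,smoking Baseline exposure prevalences per sex, named
#'   vectors `c(M=, F=)`.
#' @param obesity_trend_pp,smoking_trend_pp Trends in percentage points per
#'   year.
#' @param dm_baseline Diabetes prevalence at the model's entry age
#'   (default 0; band-level baselines follow from the hazards).
#' @return A `synthetic_country_spec` list.
#' @export
synthetic_country_spec <- function(seed = 1L,
                                   horizon = c(2000L, 2019L),
                                   bands = age_bands_core()[1:3, ],
                                   base_pop = 1e5,
                                   growth = 0.02,
                                   incidence = 0.02,
                                   m0 = 0.005,
                                   excess = 0.01,
                                   obesity = c(M = 0.25, F = 0.30),
                                   smoking = c(M = 0.40, F = 0.15),
                                   obesity_trend_pp = 0.5,
                                   smoking_trend_pp = 0,
                                   dm_baseline = 0) {
  strata <- tidyr::crossing(bands[c("age_lower", "age_upper")],
    sex = c("M", "F")
  )
  strata <- strata[stratum_order(strata), c("sex", "age_lower", "age_upper")]
  ns <- nrow(strata)
  spec <- list(
    seed = as.integer(seed), horizon = as.integer(horizon),
    strata = tibble::as_tibble(strata),
    base_pop = rep_len(base_pop, ns), growth = rep_len(growth, ns),
    incidence = rep_len(incidence, ns), m0 = rep_len(m0, ns),
    excess = rep_len(excess, ns),
    obesity = obesity, smoking = smoking,
    obesity_trend_pp = obesity_trend_pp,
    smoking_trend_pp = smoking_trend_pp,
    dm_baseline = dm_baseline
  )
  bad <- spec$incidence + spec$m0 > 1 | spec$m0 + spec$excess > 1
  if (any(spec$incidence < 0 | spec$m0 < 0 | spec$excess < 0)) {
    stop("hazards must be >= 0", call. = FALSE)
  }
  if (any(bad)) {
    stop("hazards imply per-cycle transition probability > 1 in stratum ",
      paste(strata$sex[bad], strata$age_lower[bad], collapse = "; "),
      call. = FALSE
    )
  }
  structure(spec, class = "synthetic_country_spec")
}

#' Generate a synthetic input bundle with ground truth
#'
#' Produces every table the projection pipeline consumes — population
#' anchors, baseline prevalence surface, all-cause mortality schedule,
#' risk-factor baselines — together with a ground-truth record holding the
#' generating hazards and the analytically implied band-midpoint prevalence
#' curve (from the single-year illness-death recursion
#' `S' = S(1-i-m0)`, `C' = C(1-m0-e) + S i`). Deterministic: the same spec
#' always yields an identical bundle.
#'
#' @param spec A [synthetic_country_spec()].
#' @param dir Optional directory; when given, the bundle tables are also
#'   written as CSV files mirroring the pipeline's input layout.
#' @return A list with elements `population` (anchor years), `prevalence`,
#'   `mortality`, `risk_factors`, `truth` (hazards + implied prevalence and
#'   all-cause mortality per stratum) and `config` (a ready-to-run
#'   `impact_config`).
#' @export
generate_country <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_country_spec"))
  strata <- spec$strata
  ns <- nrow(strata)
  years <- spec$horizon[1]:spec$horizon[2]

  # analytic prevalence at band midpoints from the generating recursion
  prev <- numeric(ns)
  for (s in c("M", "F")) {
    sel <- which(strata$sex == s)
    sel <- sel[order(strata$age_lower[sel])]
    prev[sel] <- prevalence_from_rates(
      spec$incidence[sel], spec$m0[sel], spec$excess[sel],
      strata$age_lower[sel], strata$age_upper[sel],
      p0 = spec$dm_baseline
    )
  }

  span <- spec$horizon[2] - spec$horizon[1]
  population <- dplyr::bind_rows(
    tibble::tibble(strata, year = spec$horizon[1], count = spec$base_pop),
    tibble::tibble(strata,
      year = spec$horizon[2],
      count = spec$base_pop * (1 + spec$growth)^span
    )
  )[c("year", "sex", "age_lower", "age_upper", "count")]

  prevalence <- tibble::tibble(strata, prevalence = prev)
  # all-cause mortality consistent with the generating hazards
  mortality <- tibble::tibble(strata,
    rate = spec$m0 * (1 - prev) + (spec$m0 + spec$excess) * prev
  )
  risk <- tibble::tibble(strata,
    obesity = unname(spec$obesity[strata$sex]),
    smoking = unname(spec$smoking[strata$sex]),
    obesity_trend_pp = spec$obesity_trend_pp,
    smoking_trend_pp = spec$smoking_trend_pp
  )
  truth <- tibble::tibble(strata,
    incidence = spec$incidence, m0 = spec$m0, excess = spec$excess,
    prevalence_midpoint = prev,
    mortality_all_cause = mortality$rate
  )

  config <- projection_config(
    horizon = spec$horizon,
    population = population,
    baseline_prevalence = prevalence,
    mortality = mortality,
    incidence = tibble::tibble(strata, incidence = spec$incidence),
    relative_risks = list(
      mort_dm = (spec$m0[1] + spec$excess[1]) / spec$m0[1],
      dm_obese = 2, dm_smoker = 1.3, joint = "multiplicative"
    ),
    risk_factors = risk,
    rate_type = "hazard"
  )

  bundle <- list(
    population = population, prevalence = prevalence,
    mortality = mortality, risk_factors = risk,
    truth = truth, config = config, spec = spec
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_population_csv(population, file.path(dir, "population.csv"))
    readr::write_csv(prevalence, file.path(dir, "prevalence.csv"))
    readr::write_csv(mortality, file.path(dir, "mortality.csv"))
    readr::write_csv(risk, file.path(dir, "risk_factors.csv"))
    readr::write_csv(truth, file.path(dir, "ground_truth.csv"))
  }
  bundle
}

#' Perturb a synthetic bundle with multiplicative noise
#'
#' Applies lognormal multiplicative noise (`exp(rnorm(0, sigma))`) to the
#' bundle's rate and prevalence tables, clipping proportions back into
#' \[0, 1\]. `sigma = 0` returns the bundle unchanged. The engine itself is
#' never perturbed — noise models measurement error in the inputs only.
#'
#' @param bundle Output of [generate_country()].
#' @param sigma Lognormal sigma(s); a single value or a named list with
#'   elements among `prevalence`, `mortality`.
#' @param seed Integer seed; perturbation is reproducible.
#' @return A bundle of the same shape with noisy `prevalence`, `mortality`
#'   and a rebuilt `config`.
#' @export
perturb_bundle <- function(bundle, sigma, seed = bundle$spec$seed) {
  if (is.numeric(sigma) && length(sigma) == 1) {
    sigma <- list(prevalence = sigma, mortality = sigma)
  }
  if (all(unlist(sigma) == 0)) {
    return(bundle)
  }
  set.seed(seed)
  out <- bundle
  n <- nrow(bundle$prevalence)
  out$prevalence$prevalence <- pmin(1, pmax(
    0, bundle$prevalence$prevalence * exp(stats::rnorm(n, 0, sigma$prevalence))
  ))
  out$mortality$rate <- pmax(
    0, bundle$mortality$rate * exp(stats::rnorm(n, 0, sigma$mortality))
  )
  out$config$baseline_prevalence <- out$prevalence
  out$config$mortality <- out$mortality
  out
}
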