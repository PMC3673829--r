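# Fixture builders shared across the test files. Everything is generated in
# code; no binary fixtures.

# A closed-population, single-stratum configuration with directly chosen
# illness-death probabilities (i, m0, e). The all-cause rate and mortality
# RR are constructed so that the Barendregt partition recovers m0 and e
# exactly. The single band is open-ended, so there is no band aging, and
# all exposure RRs are 1, so every compartment receives `i`.
single_stratum_config <- function(i, m0, e, n = 1e5, p0 = 0.1,
                                  horizon = c(2000, 2019),
                                  obesity = 0.3, smoking = 0.2,
                                  obesity_trend_pp = 0,
                                  smoking_trend_pp = 0,
                                  rr_obese = 1, rr_smoker = 1) {
  strata <- tibble::tibble(
    sex = c("M", "F"), age_lower = 25L, age_upper = NA_integer_
  )
  m_all <- (1 - p0) * m0 + p0 * (m0 + e)
  rr_mort <- if (e == 0) 1 else (m0 + e) / m0
  projection_config(
    horizon = horizon,
    population = tibble::tibble(strata, year = horizon[1], count = n),
    baseline_prevalence = tibble::tibble(strata, prevalence = p0),
    mortality = tibble::tibble(strata, rate = m_all),
    incidence = tibble::tibble(strata, incidence = i),
    relative_risks = list(
      mort_dm = rr_mort, dm_obese = rr_obese, dm_smoker = rr_smoker,
      joint = "multiplicative"
    ),
    risk_factors = tibble::tibble(
      strata,
      obesity = obesity, smoking = smoking,
      obesity_trend_pp = obesity_trend_pp,
      smoking_trend_pp = smoking_trend_pp
    ),
    rate_type = "probability",
    demography_mode = "closed"
  )
}

# Closed-form occupancy of the two-compartment illness-death system under
# the engine's cycle convention (deaths first, then incidence):
#   S_{t+1} = S_t (1-m0)(1-i),  C_{t+1} = C_t (1-m0-e) + S_t (1-m0) i
closed_form_cases <- function(t, S0, C0, i, m0, e) {
  lam_c <- 1 - m0 - e
  lam_s <- (1 - m0) * (1 - i)
  f <- i * (1 - m0)
  if (abs(lam_c - lam_s) < 1e-12) {
    lam_c^t * C0 + f * S0 * t * lam_c^(t - 1)
  } else {
    lam_c^t * C0 + f * S0 * (lam_c^t - lam_s^t) / (lam_c - lam_s)
  }
}

closed_form_susceptible <- function(t, S0, i, m0) {
  S0 * ((1 - m0) * (1 - i))^t
}

# The Syria preset objects are used by several files; build them once.
syria_cfg <- syria_preset()
syria_proj <- run_projection(syria_cfg)
syria_interv <- run_scenario(syria_cfg)

overall_prev <- function(proj, year) {
  t <- proj$totals
  100 * t$prevalence[t$sex == "all" & t$year == year]
}

sex_prev <- function(proj, year, sex) {
  t <- proj$totals
  100 * t$prevalence[t$sex == sex & t$year == year]
}
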