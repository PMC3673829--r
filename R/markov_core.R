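#' @importFrom rlang .data
NULL

# Compartment layout used throughout the engine. The first four are the
# mutually exclusive exposure ("starting") states of the non-diabetic
# population; diabetes has no outflow except to the two absorbing death
# states (no remission).
COMPARTMENTS <- c(
  "healthy", "obese_only", "smoker_only", "obese_smoker",
  "diabetes", "dead_dm", "dead_other"
)
LIVING <- 1:5
EXPOSURE <- 1:4

#' Split a non-diabetic pool into exposure compartments
#'
#' Under independence of obesity and smoking within a stratum, the
#' non-diabetic pool splits into shares
#' `(1-qo)(1-qs), qo(1-qs), (1-qo)qs, qo*qs` for
#' healthy / obese-only / smoker-only / obese-smoker. The shares sum to 1
#' and reproduce the marginal exposure prevalences exactly.
#'
#' @param q_obese,q_smoker Exposure prevalences among the non-diabetic
#'   (proportions in \[0, 1\]). Vectorised.
#' @return A matrix with one row per stratum and columns `healthy`,
#'   `obese_only`, `smoker_only`, `obese_smoker`.
#' @export
exposure_shares <- function(q_obese, q_smoker) {
  if (any(q_obese < 0 | q_obese > 1 | q_smoker < 0 | q_smoker > 1)) {
    stop("exposure prevalences must lie in [0, 1]", call. = FALSE)
  }
  out <- cbind(
    healthy = (1 - q_obese) * (1 - q_smoker),
    obese_only = q_obese * (1 - q_smoker),
    smoker_only = (1 - q_obese) * q_smoker,
    obese_smoker = q_obese * q_smoker
  )
  if (any(out < 0)) stop("negative exposure compartment", call. = FALSE)
  out
}

#' Initialize the model state
#'
#' Builds the starting-state occupancies for every stratum: the diabetic
#' pool from the baseline diabetes prevalence, and the non-diabetic pool
#' split into the four exposure compartments via [exposure_shares()].
#'
#' @param pop Population table for the baseline year (`sex`, `age_lower`,
#'   `age_upper`, `count`).
#' @param diabetes_prev Data frame aligned on (`sex`, `age_lower`) with
#'   column `prevalence` (proportion).
#' @param risk Data frame aligned on (`sex`, `age_lower`) with columns
#'   `obesity` and `smoking` (prevalences among the non-diabetic,
#'   proportions).
#' @return A state matrix (strata x compartments) with attribute `strata`
#'   (tibble `sex`, `age_lower`, `age_upper`).
#' @export
initialize_states <- function(pop, diabetes_prev, risk) {
  strata <- pop[c("sex", "age_lower", "age_upper")]
  strata <- strata[stratum_order(strata), ]
  key <- paste(strata$sex, strata$age_lower)
  n <- pop$count[match(key, paste(pop$sex, pop$age_lower))]
  p <- diabetes_prev$prevalence[
    match(key, paste(diabetes_prev$sex, diabetes_prev$age_lower))
  ]
  qo <- risk$obesity[match(key, paste(risk$sex, risk$age_lower))]
  qs <- risk$smoking[match(key, paste(risk$sex, risk$age_lower))]
  if (anyNA(n) || anyNA(p) || anyNA(qo) || anyNA(qs)) {
    stop("population, prevalence and risk tables must cover every stratum",
      call. = FALSE
    )
  }
  if (any(p < 0 | p > 1)) stop("diabetes prevalence outside [0, 1]", call. = FALSE)
  state <- matrix(0, nrow(strata), length(COMPARTMENTS),
    dimnames = list(NULL, COMPARTMENTS)
  )
  non_dm <- n * (1 - p)
  state[, EXPOSURE] <- exposure_shares(qo, qs) * non_dm
  state[, "diabetes"] <- n * p
  attr(state, "strata") <- tibble::as_tibble(strata)
  state
}

#' Exposure-specific incidence from a population incidence
#'
#' Distributes a stratum's population incidence over the exposure
#' compartments according to relative risks, holding the share-weighted mean
#' equal to the population incidence: the reference (healthy) incidence is
#' `i_ref = i_pop / sum(share_g * RR_g)` with `RR_healthy = 1` and, under
#' the default multiplicative joint action,
#' `RR_obese_smoker = rr_dm_obese * rr_dm_smoker`.
#'
#' @param i_pop Population incidence (hazard or annual probability) >= 0.
#' @param shares Length-4 vector of exposure shares among the non-diabetic
#'   (summing to 1), ordered healthy / obese-only / smoker-only /
#'   obese-smoker.
#' @param rr_obese,rr_smoker Incidence relative risks (> 0).
#' @param joint `"multiplicative"` (default) or `"max"` for the joint
#'   obese-smoker relative risk.
#' @return Named numeric vector of per-compartment incidences.
#' @export
#' @examples
#' exposure_specific_incidence(0.01, c(0.5, 0.3, 0.2, 0), 2, 1.5)
exposure_specific_incidence <- function(i_pop, shares, rr_obese, rr_smoker,
                                        joint = c("multiplicative", "max")) {
  joint <- match.arg(joint)
  if (i_pop < 0) stop("`i_pop` must be >= 0", call. = FALSE)
  if (rr_obese <= 0 || rr_smoker <= 0) stop("RRs must be > 0", call. = FALSE)
  if (abs(sum(shares) - 1) > 1e-8) stop("shares must sum to 1", call. = FALSE)
  rr_joint <- if (joint == "multiplicative") rr_obese * rr_smoker
  else max(rr_obese, rr_smoker)
  rr <- c(1, rr_obese, rr_smoker, rr_joint)
  i_ref <- i_pop / sum(shares * rr)
  out <- i_ref * rr
  if (any(out > 1)) {
    stop("exposure-specific incidence exceeds 1 per cycle; review the ",
      "cycle length or relative-risk parameters",
      call. = FALSE
    )
  }
  names(out) <- COMPARTMENTS[EXPOSURE]
  out
}

#' Apply risk-factor trend rules
#'
#' Obesity follows an absolute percentage-point annual trend capped at a
#' ceiling prevalence; smoking follows its own (default zero) trend. Both
#' are clipped to \[0, 1\].
#'
#' @param risk Data frame with columns `obesity`, `smoking` (baseline
#'   proportions), `obesity_trend_pp`, `smoking_trend_pp` (percentage points
#'   per year).
#' @param years_elapsed Years since baseline (>= 0).
#' @param obesity_cap Ceiling for obesity prevalence (proportion).
#' @return The risk table with `obesity` and `smoking` updated.
#' @export
apply_risk_trend <- function(risk, years_elapsed, obesity_cap = 0.80) {
  stopifnot(years_elapsed >= 0)
  out <- risk
  out$obesity <- pmin(
    obesity_cap,
    pmax(0, risk$obesity + risk$obesity_trend_pp / 100 * years_elapsed)
  )
  out$smoking <- pmin(
    1, pmax(0, risk$smoking + risk$smoking_trend_pp / 100 * years_elapsed)
  )
  out
}

#' Advance the model state by one annual cycle
#'
#' Order of operations within a cycle (fixed; changing it changes results):
#' 1. deaths leave every living compartment (the diabetes compartment loses
#'    both background and excess deaths, accumulated separately into the two
#'    absorbing states);
#' 2. incident cases move from each exposure compartment to diabetes;
#' 3. band aging advances a fraction `1/width` of each living compartment to
#'    the next band (none out of the open-ended band);
#' 4. entrants join the youngest band, diabetes-free; in anchored mode the
#'    living population of every band is reconciled to the externally
#'    supplied next-year count (diabetes cases are kept as computed, the
#'    non-diabetic pool absorbs the demographic change) and entrants per sex
#'    are the implied top-up;
#' 5. the non-diabetic pool is re-split to the trend-updated exposure
#'    prevalences (never touching the diabetes compartment).
#'
#' @param state State matrix from [initialize_states()] or a previous step.
#' @param trans List with matrices/vectors per stratum: `p_death_other`
#'   (background annual death probability), `p_death_dm_excess` (excess
#'   death probability from diabetes), `p_incidence` (strata x 4 exposure
#'   compartments).
#' @param widths Band widths in years (per stratum) for the `1/w` aging
#'   fraction.
#' @param next_pop Optional numeric vector: target living population per
#'   stratum for the end of the cycle (anchored mode). `NULL` = closed
#'   population.
#' @param entrants Named vector (M, F) of entrants for closed mode; ignored
#'   in anchored mode where entrants are derived.
#' @param exposure_next Optional data frame with `obesity`, `smoking` per
#'   stratum for the end-of-cycle rebalance; `NULL` skips rebalancing.
#' @return The new state matrix, with attributes `entrants` (per sex) and
#'   `new_deaths` (per sex).
#' @export
step_one_cycle <- function(state, trans, widths, next_pop = NULL,
                           entrants = c(M = 0, F = 0),
                           exposure_next = NULL) {
  strata <- attr(state, "strata")
  ns <- nrow(state)
  new <- state

  # 1. deaths
  d_other <- new[, LIVING] * trans$p_death_other
  d_dm <- new[, "diabetes"] * trans$p_death_dm_excess
  new[, LIVING] <- new[, LIVING] - d_other
  new[, "diabetes"] <- new[, "diabetes"] - d_dm
  new[, "dead_other"] <- new[, "dead_other"] + rowSums(d_other)
  new[, "dead_dm"] <- new[, "dead_dm"] + d_dm
  deaths_cycle <- rowSums(d_other) + d_dm

  # 2. incidence
  inc <- new[, EXPOSURE] * trans$p_incidence
  new[, EXPOSURE] <- new[, EXPOSURE] - inc
  new[, "diabetes"] <- new[, "diabetes"] + rowSums(inc)

  # 3. band aging (oldest band of each sex has no outflow)
  frac <- 1 / widths
  for (s in c("M", "F")) {
    idx <- which(strata$sex == s)
    idx <- idx[order(strata$age_lower[idx])]
    moved <- new[idx, LIVING, drop = FALSE] * frac[idx]
    moved[length(idx), ] <- 0
    new[idx, LIVING] <- new[idx, LIVING] - moved
    if (length(idx) > 1) {
      new[idx[-1], LIVING] <- new[idx[-1], LIVING] +
        moved[-length(idx), , drop = FALSE]
    }
  }

  # 4. entrants / demographic reconciliation
  entrants_out <- c(M = 0, F = 0)
  if (is.null(next_pop)) {
    for (s in c("M", "F")) {
      idx <- which(strata$sex == s)
      youngest <- idx[which.min(strata$age_lower[idx])]
      e <- entrants[[s]]
      entrants_out[s] <- e
      if (e != 0) {
        share <- new[youngest, EXPOSURE]
        tot <- sum(share)
        share <- if (tot > 0) share / tot else c(1, 0, 0, 0)
        new[youngest, EXPOSURE] <- new[youngest, EXPOSURE] + e * share
      }
    }
  } else {
    living_now <- rowSums(new[, LIVING, drop = FALSE])
    for (s in c("M", "F")) {
      idx <- which(strata$sex == s)
      entrants_out[s] <- sum(next_pop[idx]) - sum(living_now[idx])
    }
    over <- new[, "diabetes"] > next_pop
    if (any(over)) {
      stop("diabetes cases exceed the anchored population in stratum ",
        paste(strata$sex[over], strata$age_lower[over], collapse = "; "),
        call. = FALSE
      )
    }
    non_dm_target <- next_pop - new[, "diabetes"]
    expo <- new[, EXPOSURE, drop = FALSE]
    expo_tot <- rowSums(expo)
    share <- expo / ifelse(expo_tot > 0, expo_tot, 1)
    share[expo_tot == 0, ] <- rep(c(1, 0, 0, 0), each = sum(expo_tot == 0))
    new[, EXPOSURE] <- share * non_dm_target
  }

  # 5. exposure rebalance to trend-updated prevalences
  if (!is.null(exposure_next)) {
    non_dm <- rowSums(new[, EXPOSURE, drop = FALSE])
    new[, EXPOSURE] <- exposure_shares(
      exposure_next$obesity, exposure_next$smoking
    ) * non_dm
  }

  if (any(new[, LIVING] < -1e-9)) {
    bad <- which(new[, LIVING] < -1e-9, arr.ind = TRUE)
    stop("negative occupancy in stratum ",
      strata$sex[bad[1, 1]], " ", strata$age_lower[bad[1, 1]],
      ", compartment ", COMPARTMENTS[LIVING][bad[1, 2]],
      call. = FALSE
    )
  }
  new[, LIVING][new[, LIVING] < 0] <- 0

  attr(new, "strata") <- strata
  attr(new, "entrants") <- entrants_out
  attr(new, "new_deaths") <- vapply(
    c(M = "M", F = "F"),
    function(s) sum(deaths_cycle[strata$sex == s]), numeric(1)
  )
  new
}

# hazard -> annual probability, identity for probability-typed inputs
as_annual_prob <- function(x, rate_type) {
  if (rate_type == "hazard") 1 - exp(-x) else x
}

#' Run the full multi-year projection
#'
#' Executes the annual-cycle Markov model over the configured horizon and
#' returns the complete compartment trajectories plus derived
#' prevalence/count tables. Deterministic: identical configuration yields
#' bit-identical output.
#'
#' @param config An `impact_config` object, see [projection_config()].
#' @param scenario Optional [scenario_spec()] applied to the exposure
#'   trajectories (`NULL` = baseline run).
#' @return An object of class `impact_projection`: a list with `states`
#'   (3-d array strata x compartments x years), `strata`, `years`,
#'   `derived` (tidy tibble with population, cases and prevalence per
#'   stratum-year), `totals` (per sex and overall), `entrants`, `config`.
#' @export
run_projection <- function(config, scenario = NULL) {
  validate_config(config)
  years <- config$horizon[1]:config$horizon[2]
  ny <- length(years)

  strata <- config$baseline_prevalence[c("sex", "age_lower", "age_upper")]
  strata <- strata[stratum_order(strata), ]
  key <- paste(strata$sex, strata$age_lower)
  ns <- nrow(strata)
  widths <- band_width(strata$age_lower, strata$age_upper)

  # demography
  anchored <- identical(config$demography_mode, "anchored")
  if (anchored) {
    pop <- build_population_trajectory(config$population, years)
  } else {
    pop <- config$population[config$population$year == years[1], ]
    if (!nrow(pop)) {
      stop("closed mode needs population counts at the first horizon year",
        call. = FALSE
      )
    }
  }
  pop_at <- function(y) {
    sub <- pop[pop$year == y, ]
    sub$count[match(key, paste(sub$sex, sub$age_lower))]
  }

  # rates
  p0 <- config$baseline_prevalence$prevalence[
    match(key, paste(
      config$baseline_prevalence$sex, config$baseline_prevalence$age_lower
    ))
  ]
  m <- config$mortality$rate[
    match(key, paste(config$mortality$sex, config$mortality$age_lower))
  ]
  part <- partition_mortality(m, p0, config$relative_risks$mort_dm)
  m0 <- part$m0
  e <- part$m1 - part$m0

  i_pop <- resolve_incidence(config, strata, m0, e)

  # risk-factor table aligned to strata
  risk0 <- config$risk_factors
  ridx <- match(key, paste(risk0$sex, risk0$age_lower))
  risk0 <- risk0[ridx, ]

  # baseline exposure shares calibrate the reference incidence once
  shares0 <- exposure_shares(risk0$obesity, risk0$smoking)
  rr <- config$relative_risks
  rr_joint <- if (identical(rr$joint, "max")) {
    max(rr$dm_obese, rr$dm_smoker)
  } else {
    rr$dm_obese * rr$dm_smoker
  }
  rr_vec <- c(1, rr$dm_obese, rr$dm_smoker, rr_joint)
  i_ref <- i_pop / as.vector(shares0 %*% rr_vec)
  p_inc <- as_annual_prob(
    matrix(i_ref, ns, 4) * matrix(rr_vec, ns, 4, byrow = TRUE),
    config$rate_type
  )
  if (any(p_inc > 1)) {
    stop("per-compartment incidence probability exceeds 1; review ",
      "relative-risk and incidence inputs",
      call. = FALSE
    )
  }
  if (config$rate_type == "hazard") {
    p_total_death_dm <- 1 - exp(-(m0 + e))
    p_death_other <- 1 - exp(-m0)
    p_death_dm_excess <- p_total_death_dm - p_death_other
  } else {
    p_death_other <- m0
    p_death_dm_excess <- e
  }
  trans <- list(
    p_death_other = matrix(p_death_other, ns, length(LIVING)),
    p_death_dm_excess = p_death_dm_excess,
    p_incidence = p_inc
  )

  exposure_at <- function(t_elapsed) {
    rk <- apply_risk_trend(risk0, t_elapsed, config$obesity_cap)
    if (!is.null(scenario)) {
      rk <- apply_intervention(rk, scenario, years[1] + t_elapsed)
    }
    rk
  }

  state <- initialize_states(
    tibble::tibble(strata, count = pop_at(years[1])),
    tibble::tibble(strata, prevalence = p0),
    exposure_at(0)
  )

  states <- array(0, c(ns, length(COMPARTMENTS), ny),
    dimnames = list(NULL, COMPARTMENTS, years)
  )
  states[, , 1] <- state
  entrants <- matrix(0, ny, 2, dimnames = list(years, c("M", "F")))

  for (j in seq_len(ny - 1)) {
    state <- step_one_cycle(
      state, trans, widths,
      next_pop = if (anchored) pop_at(years[j + 1]) else NULL,
      entrants = config$closed_entrants,
      exposure_next = exposure_at(j)
    )
    states[, , j + 1] <- state
    entrants[j + 1, ] <- attr(state, "entrants")
  }

  derived <- derive_tables(states, strata, years)
  structure(
    list(
      states = states, strata = strata, years = years,
      derived = derived$bands, totals = derived$totals,
      entrants = entrants, config = config, scenario = scenario
    ),
    class = "impact_projection"
  )
}

# tidy per-stratum and total prevalence/count tables from the state array
derive_tables <- function(states, strata, years) {
  ns <- nrow(strata)
  long <- do.call(rbind, lapply(seq_along(years), function(j) {
    living <- rowSums(matrix(states[, LIVING, j], ns))
    cases <- states[, "diabetes", j]
    tibble::tibble(
      year = years[j], sex = strata$sex,
      age_lower = strata$age_lower, age_upper = strata$age_upper,
      population = living, cases = cases,
      prevalence = ifelse(living > 0, cases / living, 0)
    )
  }))
  by_sex <- dplyr::summarise(
    dplyr::group_by(long, .data$year, .data$sex),
    population = sum(.data$population), cases = sum(.data$cases),
    .groups = "drop"
  )
  by_sex$prevalence <- by_sex$cases / by_sex$population
  overall <- dplyr::summarise(
    dplyr::group_by(long, .data$year),
    population = sum(.data$population), cases = sum(.data$cases),
    .groups = "drop"
  )
  overall$sex <- "all"
  overall$prevalence <- overall$cases / overall$population
  totals <- dplyr::bind_rows(by_sex, overall)
  totals <- totals[order(totals$year, match(totals$sex, c("M", "F", "all"))), ]
  list(bands = tibble::as_tibble(long), totals = tibble::as_tibble(totals))
}

# resolve the per-stratum population incidence from the config
resolve_incidence <- function(config, strata, m0, e) {
  spec <- config$incidence
  key <- paste(strata$sex, strata$age_lower)
  if (is.data.frame(spec)) {
    i <- spec$incidence[match(key, paste(spec$sex, spec$age_lower))]
    if (anyNA(i)) stop("incidence table missing strata", call. = FALSE)
    return(i)
  }
  if (identical(spec$type, "uniform_by_sex")) {
    return(unname(spec$per_100k[strata$sex] / 1e5))
  }
  if (identical(spec$type, "estimate")) {
    out <- numeric(nrow(strata))
    bp <- config$baseline_prevalence
    for (s in unique(strata$sex)) {
      sel <- which(strata$sex == s)
      sel <- sel[order(strata$age_lower[sel])]
      p_sel <- bp$prevalence[match(
        paste(s, strata$age_lower[sel]), paste(bp$sex, bp$age_lower)
      )]
      est <- estimate_incidence_from_prevalence(
        p_sel, m0[sel], e[sel],
        strata$age_lower[sel], strata$age_upper[sel]
      )
      out[sel] <- est$incidence
    }
    return(out)
  }
  stop("unknown incidence specification", call. = FALSE)
}

#' @export
print.impact_projection <- function(x, ...) {
  yr <- range(x$years)
  tot <- x$totals[x$totals$sex == "all", ]
  first <- tot[tot$year == yr[1], ]
  last <- tot[tot$year == yr[2], ]
  cat("<impact_projection> ", yr[1], "-", yr[2], ", ",
    nrow(x$strata), " strata\n",
    sep = ""
  )
  cat(sprintf(
    "  prevalence %s: %.1f%% (%s cases)  ->  %s: %.1f%% (%s cases)\n",
    yr[1], 100 * first$prevalence, format(round(first$cases), big.mark = ","),
    yr[2], 100 * last$prevalence, format(round(last$cases), big.mark = ",")
  ))
  invisible(x)
}
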