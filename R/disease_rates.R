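#' Partition all-cause mortality by disease status (Barendregt method)
#'
#' Splits an all-cause mortality rate `m` observed in a population with
#' disease prevalence `p` into the rate among the non-diseased (`m0`) and
#' the diseased (`m1 = rr * m0`), given the mortality rate ratio `rr`
#' (diseased vs non-diseased). The closed form follows from
#' `m = (1 - p) m0 + p m1`:
#'
#' \deqn{m_0 = \frac{m}{1 - p + p \cdot rr}, \quad m_1 = rr \cdot m_0}
#'
#' The population rate attributable to the disease is
#' `p * m0 * (rr - 1)`, i.e. the excess deaths among the diseased spread
#' over the whole population.
#'
#' @param m All-cause mortality rate(s), per person-year, >= 0.
#' @param p Disease prevalence, proportion in \[0, 1\].
#' @param rr Mortality rate ratio, > 0.
#' @return A tibble with columns `m0`, `m1`, `attributable` (all rates per
#'   person-year). Vectorised over its arguments.
#' @export
#' @examples
#' partition_mortality(0.01, 0.1, 2)
partition_mortality <- function(m, p, rr) {
  if (any(rr <= 0)) stop("`rr` must be > 0", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("`p` must lie in [0, 1]", call. = FALSE)
  if (any(m < 0)) stop("`m` must be >= 0", call. = FALSE)
  m0 <- m / (1 - p + p * rr)
  tibble::tibble(m0 = m0, m1 = rr * m0, attributable = p * m0 * (rr - 1))
}

#' Excess (disease-related) mortality hazard
#'
#' Convenience wrapper: `e = m1 - m0 = m0 (rr - 1)` from the Barendregt
#' partition.
#'
#' @inheritParams partition_mortality
#' @return Numeric vector of excess hazards per person-year.
#' @export
excess_mortality <- function(m, p, rr) {
  part <- partition_mortality(m, p, rr)
  part$m1 - part$m0
}

#' Back-calculate age-specific incidence from a cross-sectional prevalence
#' curve
#'
#' Implements the illness-death ("DisMod"-style) consistency logic for a
#' chronic disease with zero remission. A synthetic single-year cohort is
#' run up the age axis with the discrete recursion
#' `S' = S (1 - i - m0)`, `C' = C (1 - m0 - e) + S i`, `p(a) = C / (S + C)`,
#' and within each age band the constant incidence hazard `i` is solved (by
#' bisection) so that the modelled prevalence matches the observed value at
#' the band midpoint. Bands are swept youngest to oldest, so each band's
#' solution conditions on the cohort state produced by the younger bands.
#' Where the observed curve declines faster than excess mortality can
#' explain, no non-negative incidence fits; incidence is floored at 0 and a
#' diagnostic message emitted.
#'
#' @param prevalence Observed prevalence (proportion) per band, ordered by
#'   age; all in \[0, 1).
#' @param m0 Background (non-diseased) mortality hazard per band, per
#'   person-year.
#' @param e Excess mortality hazard among the diseased per band, per
#'   person-year.
#' @param age_lower,age_upper Band boundaries (see [age_bands_core()]);
#'   `age_upper = NA` marks the final open-ended band.
#' @param open_width Nominal width of the open-ended band (years).
#' @param p0 Prevalence at the exact lower age bound of the first band
#'   (default 0: disease starts accumulating at model entry).
#' @param tol Bisection tolerance on the prevalence match.
#' @param max_iter Bisection iteration cap; non-convergence is an error
#'   naming the offending band.
#' @return A tibble `age_lower`, `age_upper`, `incidence` (hazard per
#'   person-year), plus attribute `"floored"` (logical per band).
#' @export
estimate_incidence_from_prevalence <- function(prevalence, m0, e,
                                               age_lower, age_upper,
                                               open_width = 10, p0 = 0,
                                               tol = 1e-10, max_iter = 200) {
  n <- length(prevalence)
  stopifnot(
    length(m0) == n, length(e) == n, length(age_lower) == n,
    length(age_upper) == n
  )
  if (any(prevalence < 0 | prevalence >= 1)) {
    stop("prevalence must lie in [0, 1)", call. = FALSE)
  }
  if (is.unsorted(age_lower)) stop("bands must be ordered by age", call. = FALSE)
  w <- band_width(age_lower, age_upper, open_width)

  # cohort state at the running age: proportions still alive in S and C
  S <- 1 - p0
  C <- p0
  incidence <- numeric(n)
  floored <- logical(n)

  advance <- function(S, C, i, m0b, eb, steps) {
    for (k in seq_len(steps)) {
      S_new <- S * (1 - i - m0b)
      C_new <- C * (1 - m0b - eb) + S * i
      S <- S_new; C <- C_new
    }
    c(S = S, C = C)
  }

  for (b in seq_len(n)) {
    half <- floor(w[b] / 2) # steps from band start to midpoint
    target <- prevalence[b]
    prev_at <- function(i) {
      st <- advance(S, C, i, m0[b], e[b], half)
      st[["C"]] / (st[["S"]] + st[["C"]])
    }
    f <- function(i) prev_at(i) - target
    f0 <- f(0)
    if (f0 >= 0) {
      # observed prevalence already at/below what zero incidence yields
      if (f0 > tol * 10) {
        message(
          "band ", format_age_band(age_lower[b], age_upper[b]),
          ": prevalence curve implies negative incidence; floored at 0"
        )
      }
      incidence[b] <- 0
      floored[b] <- f0 > tol * 10
    } else {
      lo <- 0; hi <- 1
      if (f(hi) < 0) {
        stop("no incidence in [0, 1] matches prevalence in band ",
          format_age_band(age_lower[b], age_upper[b]),
          call. = FALSE
        )
      }
      it <- 0
      repeat {
        it <- it + 1
        mid <- (lo + hi) / 2
        fm <- f(mid)
        if (abs(fm) < tol || (hi - lo) / 2 < tol) break
        if (it > max_iter) {
          stop("incidence root finding failed to converge in band ",
            format_age_band(age_lower[b], age_upper[b]),
            call. = FALSE
          )
        }
        if (fm < 0) lo <- mid else hi <- mid
      }
      incidence[b] <- mid
    }
    # advance the cohort through the full band at the solved incidence
    st <- advance(S, C, incidence[b], m0[b], e[b], w[b])
    S <- st[["S"]]; C <- st[["C"]]
  }

  out <- tibble::tibble(
    age_lower = age_lower, age_upper = age_upper, incidence = incidence
  )
  attr(out, "floored") <- floored
  out
}

#' Forward-simulate a prevalence curve from age-specific hazards
#'
#' The inverse companion of [estimate_incidence_from_prevalence()]: runs the
#' same single-year illness-death recursion with given incidence and
#' mortality hazards and reports the prevalence at each band midpoint.
#' Useful for round-trip validation.
#'
#' @inheritParams estimate_incidence_from_prevalence
#' @param incidence Incidence hazard per band, per person-year.
#' @return Numeric vector of prevalences at band midpoints.
#' @export
prevalence_from_rates <- function(incidence, m0, e, age_lower, age_upper,
                                  open_width = 10, p0 = 0) {
  n <- length(incidence)
  w <- band_width(age_lower, age_upper, open_width)
  S <- 1 - p0
  C <- p0
  out <- numeric(n)
  for (b in seq_len(n)) {
    half <- floor(w[b] / 2)
    Sb <- S; Cb <- C
    for (k in seq_len(w[b])) {
      S_new <- Sb * (1 - incidence[b] - m0[b])
      C_new <- Cb * (1 - m0[b] - e[b]) + Sb * incidence[b]
      Sb <- S_new; Cb <- C_new
      if (k == half) out[b] <- Cb / (Sb + Cb)
    }
    if (half == 0) out[b] <- C / (S + C)
    S <- Sb; C <- Cb
  }
  out
}

#' Deaths attributable to the disease in a population
#'
#' Sums `N * p * m0 * (rr - 1)` over strata: the number of deaths in excess
#' of background mortality among the diseased.
#'
#' @param pop Population table for one year (`sex`, `age_lower`,
#'   `age_upper`, `count`).
#' @param rates A data frame aligned on (`sex`, `age_lower`) with columns
#'   `prevalence` (proportion) and `m0` (background hazard).
#' @param rr Mortality rate ratio (> 0).
#' @return Total attributable deaths (persons per year).
#' @export
attributable_deaths <- function(pop, rates, rr) {
  key_p <- paste(pop$sex, pop$age_lower)
  key_r <- paste(rates$sex, rates$age_lower)
  if (!setequal(key_p, key_r) || anyDuplicated(key_p) || anyDuplicated(key_r)) {
    stop("population and rates tables are not aligned on (sex, age band)",
      call. = FALSE
    )
  }
  idx <- match(key_p, key_r)
  sum(pop$count * rates$prevalence[idx] * rates$m0[idx] * (rr - 1))
}

#' Convert rate tables between per-person-year and per-100,000 presentation
#'
#' @param rates A data frame whose rate columns are per person-year
#'   (`rates_to_per100k`) or per 100,000 person-years (`rates_from_per100k`).
#' @param cols Character vector of columns to convert.
#' @return The table with converted columns.
#' @export
rates_to_per100k <- function(rates, cols = intersect(
                               c("incidence", "mortality_all_cause",
                                 "excess_mortality", "m0", "m1",
                                 "attributable"),
                               names(rates)
                             )) {
  rates[cols] <- lapply(rates[cols], function(x) x * 1e5)
  rates
}

#' @rdname rates_to_per100k
#' @export
rates_from_per100k <- function(rates, cols = intersect(
                                 c("incidence", "mortality_all_cause",
                                   "excess_mortality", "m0", "m1",
                                   "attributable"),
                                 names(rates)
                               )) {
  rates[cols] <- lapply(rates[cols], function(x) x / 1e5)
  rates
}

#' Derive the full rate set for a stratified population
#'
#' Applies the Barendregt partition and the incidence back-calculation per
#' sex, producing the per-band rate table the Markov engine consumes:
#' prevalence, all-cause mortality, background mortality `m0`, excess
#' mortality `e`, and back-calculated incidence (remission fixed at 0).
#'
#' @param prevalence Data frame (`sex`, `age_lower`, `age_upper`,
#'   `prevalence` as a proportion).
#' @param mortality Data frame (`sex`, `age_lower`, `age_upper`, `rate`
#'   all-cause per person-year).
#' @param rr_mort Mortality rate ratio, diseased vs non-diseased.
#' @inheritParams estimate_incidence_from_prevalence
#' @return A tibble with columns `sex`, `age_lower`, `age_upper`,
#'   `prevalence`, `mortality_all_cause`, `m0`, `excess_mortality`,
#'   `incidence`, `remission` (all hazards per person-year).
#' @export
derive_rates <- function(prevalence, mortality, rr_mort, open_width = 10) {
  key_p <- paste(prevalence$sex, prevalence$age_lower)
  key_m <- paste(mortality$sex, mortality$age_lower)
  idx <- match(key_p, key_m)
  if (anyNA(idx)) {
    stop("mortality table is missing stratum/strata: ",
      paste(key_p[is.na(idx)], collapse = "; "),
      call. = FALSE
    )
  }
  out <- prevalence
  out$mortality_all_cause <- mortality$rate[idx]
  part <- partition_mortality(out$mortality_all_cause, out$prevalence, rr_mort)
  out$m0 <- part$m0
  out$excess_mortality <- part$m1 - part$m0
  out$incidence <- NA_real_
  for (s in unique(out$sex)) {
    sel <- which(out$sex == s)
    sel <- sel[order(out$age_lower[sel])]
    est <- estimate_incidence_from_prevalence(
      out$prevalence[sel], out$m0[sel], out$excess_mortality[sel],
      out$age_lower[sel], out$age_upper[sel],
      open_width = open_width
    )
    out$incidence[sel] <- est$incidence
  }
  out$remission <- 0
  tibble::as_tibble(out)
}

#' Crude (all-band) incidence per 100,000 population
#'
#' Population-weighted summary of age-specific incidence: new cases per year
#' per 100,000 total population, `1e5 * sum(N (1-p) i) / sum(N)`.
#'
#' @param rates Output of [derive_rates()] (needs `prevalence`, `incidence`).
#' @param pop Population table for the reference year, aligned on
#'   (`sex`, `age_lower`).
#' @param by_sex Summarise per sex (default) or overall.
#' @return A tibble `sex`, `crude_incidence_per100k` (or one overall row).
#' @export
crude_incidence <- function(rates, pop, by_sex = TRUE) {
  idx <- match(paste(rates$sex, rates$age_lower), paste(pop$sex, pop$age_lower))
  if (anyNA(idx)) stop("population table missing strata", call. = FALSE)
  n <- pop$count[idx]
  cases <- n * (1 - rates$prevalence) * rates$incidence
  grp <- if (by_sex) rates$sex else rep("all", nrow(rates))
  out <- tibble::tibble(sex = grp, cases = cases, n = n)
  out <- dplyr::summarise(dplyr::group_by(out, .data$sex),
    crude_incidence_per100k = 1e5 * sum(.data$cases) / sum(.data$n),
    .groups = "drop"
  )
  out
}
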