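test_that("mortality partition matches the closed form and conserves the
  all-cause rate", {
  part <- partition_mortality(0.01, 0.1, 2)
  expect_equal(part$m0, 0.01 / 1.1)
  expect_equal(part$m1, 0.02 / 1.1)
  expect_equal(part$attributable, 0.001 / 1.1)

  # null relative risk and zero prevalence leave mortality untouched
  expect_equal(partition_mortality(0.02, 0.3, 1)$m0, 0.02)
  expect_equal(partition_mortality(0.02, 0.3, 1)$m1, 0.02)
  expect_equal(partition_mortality(0.02, 0, 3)$m0, 0.02)
  expect_equal(partition_mortality(0.02, 0, 3)$attributable, 0)

  # conservation (1-p) m0 + p m1 = m over random draws
  set.seed(42)
  m <- runif(300, 0, 0.2)
  p <- runif(300)
  rr <- runif(300, 0.2, 6)
  part <- partition_mortality(m, p, rr)
  expect_equal((1 - p) * part$m0 + p * part$m1, m, tolerance = 1e-12)

  # m0 strictly decreases in rr for p > 0
  rr_grid <- seq(1, 5, by = 0.5)
  m0_grid <- partition_mortality(0.01, 0.2, rr_grid)$m0
  expect_true(all(diff(m0_grid) < 0))

  expect_error(partition_mortality(0.01, 0.5, 0), "rr")
  expect_error(partition_mortality(0.01, 1.2, 2), "p")
})

test_that("constant prevalence with zero excess mortality needs no new
  cases beyond the first band", {
  bands <- age_bands_core()
  est <- estimate_incidence_from_prevalence(
    prevalence = rep(0.2, 6), m0 = rep(0.01, 6), e = rep(0, 6),
    age_lower = bands$age_lower, age_upper = bands$age_upper
  )
  expect_gt(est$incidence[1], 0) # builds 0 -> 20% within the first band
  expect_equal(est$incidence[-1], rep(0, 5), tolerance = 1e-6)
})

test_that("incidence back-calculation inverts forward simulation", {
  bands <- age_bands_core()
  i_true <- c(0.002, 0.005, 0.012, 0.02, 0.015, 0.01)
  m0 <- c(0.001, 0.002, 0.005, 0.012, 0.03, 0.09)
  e <- c(0.001, 0.002, 0.004, 0.006, 0.01, 0.03)
  p <- prevalence_from_rates(i_true, m0, e, bands$age_lower, bands$age_upper)
  est <- estimate_incidence_from_prevalence(
    p, m0, e, bands$age_lower, bands$age_upper
  )
  expect_equal(est$incidence, i_true, tolerance = 1e-6)

  # round trip: re-simulated prevalence within 0.5% absolute
  p_back <- prevalence_from_rates(
    est$incidence, m0, e, bands$age_lower, bands$age_upper
  )
  expect_true(all(abs(p_back - p) < 0.005))
})

test_that("a constant-hazard cohort recovers its incidence to <1% relative
  error", {
  bands <- age_bands_core()
  i_true <- rep(0.02, 6)
  m0 <- rep(0.005, 6)
  e <- rep(0.01, 6)
  p <- prevalence_from_rates(i_true, m0, e, bands$age_lower, bands$age_upper)
  est <- estimate_incidence_from_prevalence(
    p, m0, e, bands$age_lower, bands$age_upper
  )
  expect_true(all(abs(est$incidence / 0.02 - 1) < 0.01))
})

test_that("declining prevalence beyond what mortality explains floors
  incidence at zero with a diagnostic", {
  bands <- age_bands_core()[1:3, ]
  expect_message(
    est <- estimate_incidence_from_prevalence(
      prevalence = c(0.3, 0.1, 0.05), m0 = rep(0.01, 3), e = rep(0, 3),
      age_lower = bands$age_lower, age_upper = bands$age_upper
    ),
    "negative incidence"
  )
  expect_equal(est$incidence[2:3], c(0, 0))
  expect_true(any(attr(est, "floored")))
})

test_that("modelled prevalence is non-decreasing in age when excess
  mortality is zero", {
  bands <- age_bands_core()
  set.seed(7)
  for (k in 1:20) {
    i <- runif(6, 0, 0.05)
    m0 <- runif(6, 0, 0.05)
    p <- prevalence_from_rates(i, m0, rep(0, 6),
      bands$age_lower, bands$age_upper
    )
    expect_true(all(diff(p) >= -1e-12))
  }
})

test_that("attributable deaths follow N p m0 (rr - 1)", {
  pop <- tibble::tibble(
    sex = "M", age_lower = 45L, age_upper = 55L, count = 1e5
  )
  rates <- tibble::tibble(
    sex = "M", age_lower = 45L, prevalence = 0.1, m0 = 0.01
  )
  expect_equal(attributable_deaths(pop, rates, 2), 100)
  expect_equal(attributable_deaths(pop, rates, 1), 0)
  expect_error(
    attributable_deaths(pop, dplyr::mutate(rates, age_lower = 55L), 2),
    "not aligned"
  )
})

test_that("per-100k conversion round-trips", {
  r <- tibble::tibble(incidence = 0.0119, m0 = 0.002)
  expect_equal(rates_from_per100k(rates_to_per100k(r)), r)
  expect_equal(rates_to_per100k(r)$incidence, 1190)
})

test_that("the Syrian 2003 curve yields incidence rising with age,
  lowest in the youngest band", {
  rates <- derive_rates(
    syria_cfg$baseline_prevalence, syria_cfg$mortality,
    rr_mort = syria_cfg$relative_risks$mort_dm
  )
  for (s in c("M", "F")) {
    sel <- rates$sex == s
    i <- rates$incidence[sel][order(rates$age_lower[sel])]
    # steep rise from the youngest band into the middle bands
    expect_lt(i[1], min(i[3:4]))
    expect_gt(max(i[3:4]) / max(i[1], 1e-9), 5)
  }
  # excess mortality rises monotonically with age for both sexes
  for (s in c("M", "F")) {
    e <- rates$excess_mortality[rates$sex == s]
    expect_true(all(diff(e) > 0))
  }
})

test_that("attributable diabetes deaths for the 2011 configuration are in
  the low thousands", {
  pop11 <- build_population_trajectory(syria_cfg$population, 2011)
  d11 <- syria_proj$derived[syria_proj$derived$year == 2011, ]
  mort <- syria_cfg$mortality
  m <- mort$rate[match(
    paste(d11$sex, d11$age_lower), paste(mort$sex, mort$age_lower)
  )]
  rr <- syria_cfg$relative_risks$mort_dm
  part <- partition_mortality(m, d11$prevalence, rr)
  rates <- tibble::tibble(
    sex = d11$sex, age_lower = d11$age_lower,
    prevalence = d11$prevalence, m0 = part$m0
  )
  deaths <- attributable_deaths(pop11, rates, rr)
  expect_gt(deaths, 1000)
  expect_lt(deaths, 15000)
})
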