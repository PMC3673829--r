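test_that("starting states split the non-diabetic pool under independence
  and reproduce the marginals", {
  # no exposure: everyone non-diabetic is healthy
  s0 <- exposure_shares(0, 0)
  expect_equal(unname(s0[1, ]), c(1, 0, 0, 0))

  # independence arithmetic
  pop <- tibble::tibble(
    sex = c("M", "F"), age_lower = 25L, age_upper = NA_integer_,
    count = c(1000, 1000)
  )
  prev <- tibble::tibble(pop[1:3], prevalence = 0)
  risk <- tibble::tibble(pop[1:3], obesity = 0.4, smoking = 0.5)
  st <- initialize_states(pop, prev, risk)
  expect_equal(unname(st[1, 1:4]), c(300, 200, 300, 200))

  # baseline survey marginals (women): diabetes 14.7%, obesity 40.1%,
  # smoking 18.8% are reproduced exactly by the initialized state
  pop_f <- tibble::tibble(
    sex = c("M", "F"), age_lower = 25L, age_upper = NA_integer_,
    count = 1e6
  )
  prev_f <- tibble::tibble(pop_f[1:3], prevalence = c(0.092, 0.147))
  risk_f <- tibble::tibble(pop_f[1:3],
    obesity = c(0.29, 0.401), smoking = c(0.591, 0.188)
  )
  st <- initialize_states(pop_f, prev_f, risk_f)
  f <- st[2, ]
  expect_equal(f[["diabetes"]] / 1e6, 0.147)
  non_dm <- sum(f[1:4])
  expect_equal((f[["obese_only"]] + f[["obese_smoker"]]) / non_dm, 0.401)
  expect_equal((f[["smoker_only"]] + f[["obese_smoker"]]) / non_dm, 0.188)
  expect_equal(non_dm + f[["diabetes"]], 1e6)
})

test_that("exposure-specific incidence preserves the population incidence", {
  # all relative risks 1: every compartment receives the population rate
  expect_equal(
    unname(exposure_specific_incidence(0.01, c(0.25, 0.25, 0.25, 0.25), 1, 1)),
    rep(0.01, 4)
  )
  # reference rate scales by the share-weighted RR
  inc <- exposure_specific_incidence(0.014, c(0.5, 0.3, 0.2, 0), 2, 1.5)
  expect_equal(inc[["healthy"]], 0.014 / 1.4)
  expect_equal(inc[["obese_only"]], 2 * 0.014 / 1.4)
  # conservation to machine precision over random draws
  set.seed(11)
  for (k in 1:50) {
    q <- runif(2)
    shares <- as.vector(exposure_shares(q[1], q[2]))
    rr <- runif(2, 0.5, 8)
    i_pop <- runif(1, 0, 0.05)
    inc <- exposure_specific_incidence(i_pop, shares, rr[1], rr[2])
    expect_equal(sum(shares * inc), i_pop, tolerance = 1e-14)
  }
  expect_error(
    exposure_specific_incidence(0.9, c(1, 0, 0, 0), 5, 5),
    "exceeds 1"
  )
})

test_that("risk-factor trends are absolute percentage points with an
  obesity cap", {
  risk <- tibble::tibble(
    obesity = c(0.29, 0.795), smoking = c(0.591, 0.1),
    obesity_trend_pp = 1, smoking_trend_pp = 0
  )
  r3 <- apply_risk_trend(risk, 3)
  expect_equal(r3$obesity[1], 0.32)
  r5 <- apply_risk_trend(risk, 5)
  expect_equal(r5$obesity[2], 0.80) # capped
  expect_equal(r5$smoking, risk$smoking) # zero trend: unchanged
  expect_equal(apply_risk_trend(risk, 0), risk)
})

test_that("a single closed stratum matches the closed-form illness-death
  solution at every cycle", {
  i <- 0.02; m0 <- 0.005; e <- 0.01; n <- 1e5; p0 <- 0.1
  cfg <- single_stratum_config(i, m0, e, n = n, p0 = p0)
  proj <- run_projection(cfg)
  t_seq <- seq_along(proj$years) - 1
  expected_cases <- closed_form_cases(t_seq, n * (1 - p0), n * p0, i, m0, e)
  got_cases <- proj$states[1, "diabetes", ]
  expect_true(all(abs(got_cases / expected_cases - 1) < 1e-3))
  expected_s <- closed_form_susceptible(t_seq, n * (1 - p0), i, m0)
  got_s <- rowSums(t(proj$states[1, 1:4, ]))
  expect_true(all(abs(got_s / expected_s - 1) < 1e-3))
})

test_that("zero incidence means diabetes can only decline; zero transitions
  freeze the state", {
  cfg <- single_stratum_config(0, 0.01, 0.02, p0 = 0.2)
  proj <- run_projection(cfg)
  expect_true(all(diff(proj$states[1, "diabetes", ]) <= 0))

  cfg0 <- single_stratum_config(0, 0, 0, p0 = 0.2)
  proj0 <- run_projection(cfg0)
  expect_equal(proj0$states[, , length(proj0$years)],
    proj0$states[, , 1],
    tolerance = 1e-12
  )
})

test_that("one cycle moves incident cases from exposure to diabetes", {
  cfg <- single_stratum_config(0.1, 0, 0, n = 1000, p0 = 0)
  proj <- run_projection(cfg)
  expect_equal(proj$states[1, "diabetes", 2], 100)
  expect_equal(sum(proj$states[1, 1:4, 2]), 900)
})

test_that("band aging moves 1/width of each living compartment", {
  # two closed bands, no deaths/incidence: the young band decays by 1/10
  strata <- tidyr::crossing(
    sex = c("M", "F"),
    tibble::tibble(age_lower = c(25L, 35L), age_upper = c(35L, NA))
  )[c("sex", "age_lower", "age_upper")]
  cfg <- projection_config(
    horizon = c(2000, 2002),
    population = tibble::tibble(strata, year = 2000L, count = 1000),
    baseline_prevalence = tibble::tibble(strata, prevalence = 0),
    mortality = tibble::tibble(strata, rate = 0),
    incidence = tibble::tibble(strata, incidence = 0),
    relative_risks = list(mort_dm = 1, dm_obese = 1, dm_smoker = 1),
    risk_factors = tibble::tibble(strata,
      obesity = 0.2, smoking = 0.2,
      obesity_trend_pp = 0, smoking_trend_pp = 0
    ),
    rate_type = "probability",
    demography_mode = "closed"
  )
  proj <- run_projection(cfg)
  d <- proj$derived
  young <- d[d$age_lower == 25 & d$sex == "M", ]
  old <- d[d$age_lower == 35 & d$sex == "M", ]
  expect_equal(young$population, 1000 * 0.9^(0:2))
  expect_equal(old$population[2], 1100)
})

test_that("persons are conserved per sex at every cycle of the anchored
  projection", {
  proj <- syria_proj
  st <- proj$states
  strata <- proj$strata
  for (s in c("M", "F")) {
    idx <- strata$sex == s
    living <- colSums(st[idx, 1:5, , drop = FALSE], dims = 2)
    dead <- colSums(st[idx, 6:7, , drop = FALSE], dims = 2)
    entrants <- proj$entrants[, s]
    balance <- diff(living + dead) - entrants[-1]
    expect_true(all(abs(balance) < 1e-5))
  }
})

test_that("death compartments never decrease", {
  st <- syria_proj$states
  expect_true(all(apply(st[, "dead_dm", ], 1, diff) >= 0))
  expect_true(all(apply(st[, "dead_other", ], 1, diff) >= 0))
})

test_that("no remission: the rebalance step never touches the diabetes
  compartment", {
  # with zero mortality the diabetes stock is non-decreasing even while
  # exposure pools are re-split every cycle by the trend rules
  cfg <- single_stratum_config(0.02, 0, 0,
    p0 = 0.1,
    obesity_trend_pp = 1, smoking_trend_pp = -0.5
  )
  proj <- run_projection(cfg)
  expect_true(all(diff(proj$states[1, "diabetes", ]) >= 0))
  expect_true(all(diff(proj$states[2, "diabetes", ]) >= 0))
})

test_that("obesity prevalence never exceeds the cap in any stratum-year", {
  cfg <- single_stratum_config(0.01, 0.002, 0.002,
    obesity = 0.75, obesity_trend_pp = 2
  )
  proj <- run_projection(cfg)
  st <- proj$states
  for (j in seq_along(proj$years)) {
    non_dm <- rowSums(st[, 1:4, j])
    obese <- st[, "obese_only", j] + st[, "obese_smoker", j]
    expect_true(all(obese / non_dm <= 0.80 + 1e-9))
  }
})

test_that("raising the obesity relative risk never lowers projected
  prevalence when obesity is rising", {
  prev_grid <- lapply(c(3, 7.19, 10), function(rr) {
    cfg <- syria_cfg
    cfg$relative_risks$dm_obese <- rr
    run_projection(cfg)$totals |>
      dplyr::filter(.data$sex == "all") |>
      dplyr::pull(.data$prevalence)
  })
  expect_true(all(prev_grid[[2]] - prev_grid[[1]] >= -1e-12))
  expect_true(all(prev_grid[[3]] - prev_grid[[2]] >= -1e-12))
})

test_that("an incomplete configuration reports every missing field at
  once", {
  cfg <- syria_cfg
  cfg$mortality <- NULL
  cfg$relative_risks$mort_dm <- NULL
  err <- tryCatch(validate_config(cfg), error = function(e) conditionMessage(e))
  expect_match(err, "mortality must be a data frame")
  expect_match(err, "relative_risks must name")
})

test_that("identical configurations yield bit-identical projections", {
  p1 <- run_projection(syria_preset())
  expect_identical(p1$states, syria_proj$states)
  expect_identical(p1$totals, syria_proj$totals)
})
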