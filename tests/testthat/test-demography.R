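test_that("geometric interpolation passes through anchors and grows at a
  constant rate", {
  anchors <- tibble::tibble(
    year = rep(c(2003L, 2005L), each = 2),
    sex = rep(c("M", "F"), 2),
    age_lower = 25L, age_upper = 35L,
    count = c(1000, 500, 1210, 500)
  )
  traj <- build_population_trajectory(anchors, 2003:2005)
  m <- traj[traj$sex == "M", ]
  expect_identical(m$count[m$year == 2003], 1000)
  expect_identical(m$count[m$year == 2005], 1210)
  # 1000 * sqrt(1.21) = 1100
  expect_equal(m$count[m$year == 2004], 1100)
  # zero growth stays flat at interior years
  f <- traj[traj$sex == "F", ]
  expect_equal(f$count, rep(500, 3))
})

test_that("a doubling anchor pair doubles over the span", {
  anchors <- tibble::tibble(
    year = c(2003L, 2022L, 2003L, 2022L),
    sex = rep(c("M", "F"), each = 2),
    age_lower = 25L, age_upper = NA_integer_,
    count = c(1000, 2000, 1000, 2000)
  )
  traj <- build_population_trajectory(anchors, 2003:2022)
  expect_equal(
    traj$count[traj$year == 2022] / traj$count[traj$year == 2003],
    c(2, 2)
  )
  # interior values follow a constant annual growth rate
  m <- traj$count[traj$sex == "M"]
  expect_true(all(abs(diff(log(m)) - log(2) / 19) < 1e-12))
})

test_that("interpolation refuses extrapolation and incomplete anchors", {
  anchors <- tibble::tibble(
    year = c(2003L, 2010L), sex = "M", age_lower = 25L, age_upper = 35L,
    count = c(1000, 1200)
  )
  expect_error(
    build_population_trajectory(anchors, 2000:2010),
    "extrapolation"
  )
  two_strata <- rbind(
    anchors,
    tibble::tibble(
      year = 2003L, sex = "F", age_lower = 25L, age_upper = 35L, count = 900
    )
  )
  expect_error(
    build_population_trajectory(two_strata, 2003:2010),
    "missing stratum"
  )
})

test_that("denominators are reconstructed as count / (prevalence/100)", {
  rep <- tibble::tibble(
    sex = c("M", "M", "F"), band = c("25-34", "25-34", "45-54"),
    year = c(2003L, 2022L, 2003L),
    count = c(16995, 249919, 0), prevalence_pct = c(1.2, 11.3, 1)
  )
  den <- reconstruct_denominators(rep)
  expect_equal(den$count[1], 16995 / 0.012)
  expect_equal(den$count[2], 249919 / 0.113)
  expect_equal(den$count[3], 0)
  expect_identical(den$age_lower, c(25L, 25L, 45L))
  expect_identical(den$age_upper, c(35L, 35L, 55L))

  expect_error(
    reconstruct_denominators(tibble::tibble(
      sex = "M", band = "25-34", year = 2003L, count = 5, prevalence_pct = 0
    )),
    "prevalence 0 with positive count"
  )
  unknown <- reconstruct_denominators(tibble::tibble(
    sex = "M", band = "25-34", year = 2003L, count = 0, prevalence_pct = 0
  ))
  expect_true(is.na(unknown$count))
})

test_that("reconstruction then re-tabulation is idempotent to printed
  rounding", {
  rep <- readr::read_csv(
    system.file("extdata", "syria_table1.csv", package = "impactdm"),
    col_types = readr::cols()
  )
  den <- reconstruct_denominators(rep)
  back <- 100 * rep$count / den$count
  expect_true(all(abs(back - rep$prevalence_pct) <= 0.05 + 1e-12))
})

test_that("cohort entry reconciles the youngest band and floors at zero", {
  pop <- tibble::tibble(
    year = rep(c(2003L, 2004L), each = 2),
    sex = rep(c("M", "F"), 2),
    age_lower = 25L, age_upper = 35L,
    count = c(1000, 1000, 1100, 1000)
  )
  ent <- cohort_entry(pop, 2004,
    aged_out = c(M = 50, F = 0), deaths = c(M = 10, F = 0)
  )
  expect_equal(ent[["M"]], 1100 - (1000 - 50 - 10))
  # stationary population, no aging or deaths -> zero entrants
  expect_equal(ent[["F"]], 0)
  expect_error(cohort_entry(pop, 2003), "no prior year")
  shrink <- pop
  shrink$count[3] <- 100
  expect_warning(
    ent2 <- cohort_entry(shrink, 2004),
    "floored at 0"
  )
  expect_equal(ent2[["M"]], 0)
})

test_that("population CSV round-trips including open-ended bands", {
  pop <- tibble::tibble(
    year = 2003L, sex = c("M", "M"), age_lower = c(25L, 75L),
    age_upper = c(35L, NA), count = c(1000.5, 77)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_population_csv(pop, path)
  expect_equal(as.data.frame(read_population_csv(path)), as.data.frame(pop))
})
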