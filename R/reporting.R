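#' Tabulate a projection in the published report layout
#'
#' Produces the "count (prevalence%)" table per sex and age band for
#' selected years, with counts rounded to integers, prevalence to one
#' decimal, and a totals row recomputed from unrounded values.
#'
#' @param result An `impact_projection`.
#' @param years Years to report (must lie within the horizon).
#' @param band_set `"core"` (the model's six bands). Unknown sets error,
#'   listing the available ones.
#' @return A tibble with columns `sex`, `band` and one character column per
#'   year.
#' @export
tabulate_report <- function(result, years = range(result$years),
                            band_set = "core") {
  if (!band_set %in% "core") {
    stop("unknown band set '", band_set, "'; available: core", call. = FALSE)
  }
  if (!all(years %in% result$years)) {
    stop("requested years outside the projection horizon", call. = FALSE)
  }
  d <- result$derived[result$derived$year %in% years, ]
  cell <- function(count, prev) {
    sprintf("%d (%s)", round(count), formatC(round(100 * prev, 1),
      format = "fg"
    ))
  }
  rows <- list()
  for (s in c("M", "F")) {
    sub <- d[d$sex == s, ]
    for (al in sort(unique(sub$age_lower))) {
      b <- sub[sub$age_lower == al, ]
      b <- b[order(b$year), ]
      rows[[length(rows) + 1]] <- c(
        sex = s, band = format_age_band(al, b$age_upper[1]),
        stats::setNames(cell(b$cases, b$prevalence), b$year)
      )
    }
    tot <- dplyr::summarise(dplyr::group_by(sub, .data$year),
      cases = sum(.data$cases), population = sum(.data$population),
      .groups = "drop"
    )
    tot <- tot[order(tot$year), ]
    rows[[length(rows) + 1]] <- c(
      sex = s, band = "total",
      stats::setNames(cell(tot$cases, tot$cases / tot$population), tot$year)
    )
  }
  tot <- dplyr::summarise(dplyr::group_by(d, .data$year),
    cases = sum(.data$cases), population = sum(.data$population),
    .groups = "drop"
  )
  tot <- tot[order(tot$year), ]
  rows[[length(rows) + 1]] <- c(
    sex = "all", band = "total",
    stats::setNames(cell(tot$cases, tot$cases / tot$population), tot$year)
  )
  tibble::as_tibble(do.call(rbind, rows))
}

#' Parse a "count (prevalence%)" report back into numbers
#'
#' Inverse of the [tabulate_report()] cell format, enabling round-trip
#' checks against published tables.
#'
#' @param report Tibble as returned by [tabulate_report()].
#' @return A long tibble `sex`, `band`, `year`, `count`, `prevalence_pct`.
#' @export
parse_report <- function(report) {
  year_cols <- setdiff(names(report), c("sex", "band"))
  long <- tidyr::pivot_longer(report, dplyr::all_of(year_cols),
    names_to = "year", values_to = "cell"
  )
  m <- regmatches(long$cell, regexec("^([0-9]+) \\(([-0-9.]+)\\)$", long$cell))
  long$count <- as.numeric(vapply(m, `[`, "", 2))
  long$prevalence_pct <- as.numeric(vapply(m, `[`, "", 3))
  long$year <- as.integer(long$year)
  long[c("sex", "band", "year", "count", "prevalence_pct")]
}

#' Recompute prevalence over the 20-79 comparison age range
#'
#' International comparisons are often published for ages 20-79. This
#' recalculation removes the >79 population from the open-ended oldest band
#' (via a configured split fraction assumed to carry the band's prevalence)
#' and adds a 20-24 population at zero diabetes prevalence.
#'
#' @param result An `impact_projection` whose oldest band is open-ended.
#' @param pop_20_24 Population table (`year`, `sex`, `count`) for ages
#'   20-24 covering the requested years.
#' @param years Years to report (default: all).
#' @param split_75_79 Fraction of the open-ended band (both cases and
#'   population) assumed to be aged 75-79 (default 0.5).
#' @return A tibble per year and sex (plus `"all"`): `population`, `cases`,
#'   `prevalence` over ages 20-79.
#' @export
idf_comparable <- function(result, pop_20_24, years = result$years,
                           split_75_79 = 0.5) {
  if (is.null(pop_20_24) || !all(years %in% unique(pop_20_24$year))) {
    stop("a 20-24 population trajectory covering the requested years ",
      "is required",
      call. = FALSE
    )
  }
  d <- result$derived[result$derived$year %in% years, ]
  open <- is.na(d$age_upper)
  d$population[open] <- d$population[open] * split_75_79
  d$cases[open] <- d$cases[open] * split_75_79
  by_sex <- dplyr::summarise(dplyr::group_by(d, .data$year, .data$sex),
    population = sum(.data$population), cases = sum(.data$cases),
    .groups = "drop"
  )
  extra <- pop_20_24[pop_20_24$year %in% years, c("year", "sex", "count")]
  idx <- match(
    paste(by_sex$year, by_sex$sex),
    paste(extra$year, extra$sex)
  )
  if (anyNA(idx)) {
    stop("20-24 population missing strata for some year/sex", call. = FALSE)
  }
  by_sex$population <- by_sex$population + extra$count[idx]
  by_sex$prevalence <- by_sex$cases / by_sex$population
  overall <- dplyr::summarise(dplyr::group_by(by_sex, .data$year),
    population = sum(.data$population), cases = sum(.data$cases),
    .groups = "drop"
  )
  overall$sex <- "all"
  overall$prevalence <- overall$cases / overall$population
  out <- dplyr::bind_rows(by_sex, overall)
  out[order(out$year, match(out$sex, c("M", "F", "all"))), ]
}

#' Relative change in percent
#'
#' `100 * (v1 - v0) / v0`.
#'
#' @param v0 Baseline value (> 0).
#' @param v1 Comparison value.
#' @return Percent change.
#' @export
#' @examples
#' relative_increase(10, 21.3)
relative_increase <- function(v0, v1) {
  if (any(v0 == 0)) stop("relative increase undefined for v0 = 0", call. = FALSE)
  100 * (v1 - v0) / v0
}

#' Fold change in band prevalence between two years
#'
#' `prevalence(y1) / prevalence(y0)` per age band, sexes combined. Bands
#' with zero baseline prevalence are flagged and excluded.
#'
#' @param result An `impact_projection`.
#' @param y0,y1 Years within the horizon.
#' @return A tibble `band`, `age_lower`, `prevalence_y0`, `prevalence_y1`,
#'   `fold`.
#' @export
fold_increase_by_band <- function(result, y0, y1) {
  stopifnot(y0 %in% result$years, y1 %in% result$years)
  d <- result$derived[result$derived$year %in% c(y0, y1), ]
  agg <- dplyr::summarise(
    dplyr::group_by(d, .data$year, .data$age_lower, .data$age_upper),
    population = sum(.data$population), cases = sum(.data$cases),
    .groups = "drop"
  )
  agg$prevalence <- agg$cases / agg$population
  a0 <- agg[agg$year == y0, ]
  a1 <- agg[agg$year == y1, ]
  idx <- match(a0$age_lower, a1$age_lower)
  out <- tibble::tibble(
    band = format_age_band(a0$age_lower, a0$age_upper),
    age_lower = a0$age_lower,
    prevalence_y0 = a0$prevalence,
    prevalence_y1 = a1$prevalence[idx],
    fold = a1$prevalence[idx] / a0$prevalence
  )
  zero <- out$prevalence_y0 == 0
  if (any(zero)) {
    warning("zero baseline prevalence; excluding band(s): ",
      paste(out$band[zero], collapse = ", "),
      call. = FALSE
    )
    out <- out[!zero, ]
  }
  out
}

#' Plot the projected prevalence trajectory by sex
#'
#' @param result An `impact_projection`.
#' @return A ggplot object.
#' @export
plot_prevalence_trend <- function(result) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  tot <- result$totals
  tot$sex <- factor(tot$sex, c("M", "F", "all"),
    c("Men", "Women", "Both sexes")
  )
  ggplot2::ggplot(
    tot,
    ggplot2::aes(.data$year, 100 * .data$prevalence, colour = .data$sex)
  ) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(
      x = "Year", y = "Diabetes prevalence (%)", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot a baseline vs intervention comparison
#'
#' @param comparison Output of [compare_scenarios()].
#' @return A ggplot object.
#' @export
plot_scenario_comparison <- function(comparison) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  long <- tidyr::pivot_longer(
    comparison[c("year", "prevalence_baseline", "prevalence_intervention")],
    -"year",
    names_to = "run", values_to = "prevalence"
  )
  long$run <- ifelse(long$run == "prevalence_baseline",
    "Baseline", "Intervention"
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(.data$year, .data$prevalence, linetype = .data$run)
  ) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Year", y = "Diabetes prevalence (%)", linetype = NULL) +
    ggplot2::theme_minimal()
}
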