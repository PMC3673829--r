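#' Interpolate an age/sex population trajectory between anchor years
#'
#' Builds a complete year-by-year population table over a projection horizon
#' from counts known only at a sparse set of anchor years (for example a
#' census year plus published projections for selected years). Between
#' consecutive anchors each stratum follows geometric interpolation, i.e. a
#' constant annual growth rate — the standard demographic convention for
#' intercensal population growth. Anchor-year values are returned exactly.
#'
#' @param anchors A data frame with columns `year`, `sex` ("M"/"F"),
#'   `age_lower`, `age_upper` (`NA` = open band) and `count` (persons,
#'   non-negative), holding at least two distinct years.
#' @param horizon Integer vector of calendar years (a contiguous range) to
#'   cover. Must lie within the span of the anchor years: extrapolation
#'   beyond the anchors is refused.
#' @return A tibble with the same columns, one row per year/sex/band.
#' @export
#' @examples
#' anchors <- tibble::tibble(
#'   year = c(2003, 2005), sex = "M", age_lower = 25, age_upper = 35,
#'   count = c(1000, 1210)
#' )
#' build_population_trajectory(anchors, 2003:2005)
build_population_trajectory <- function(anchors, horizon) {
  stopifnot(is.data.frame(anchors))
  req <- c("year", "sex", "age_lower", "age_upper", "count")
  if (!all(req %in% names(anchors))) {
    stop("anchors must have columns: ", paste(req, collapse = ", "),
      call. = FALSE
    )
  }
  check_sex(anchors$sex)
  if (any(anchors$count < 0)) stop("anchor counts must be >= 0", call. = FALSE)
  horizon <- sort(unique(as.integer(horizon)))
  yrs <- sort(unique(anchors$year))
  if (length(yrs) < 2) {
    stop("need anchors at >= 2 distinct years", call. = FALSE)
  }
  if (min(horizon) < min(yrs) || max(horizon) > max(yrs)) {
    stop(
      "horizon [", min(horizon), ", ", max(horizon),
      "] extends beyond the anchor span [", min(yrs), ", ", max(yrs),
      "]; extrapolation is refused",
      call. = FALSE
    )
  }

  strata <- unique(anchors[c("sex", "age_lower", "age_upper")])
  strata <- strata[stratum_order(strata), ]
  # every stratum must be present at every anchor year
  for (y in yrs) {
    at_y <- anchors[anchors$year == y, ]
    key_all <- paste(strata$sex, strata$age_lower, strata$age_upper)
    key_y <- paste(at_y$sex, at_y$age_lower, at_y$age_upper)
    missing <- setdiff(key_all, key_y)
    if (length(missing)) {
      stop("anchor year ", y, " is missing stratum/strata: ",
        paste(missing, collapse = "; "),
        call. = FALSE
      )
    }
  }

  interp_one <- function(sub) {
    sub <- sub[order(sub$year), ]
    out_counts <- numeric(length(horizon))
    for (j in seq_along(horizon)) {
      y <- horizon[j]
      if (y %in% sub$year) {
        out_counts[j] <- sub$count[sub$year == y]
      } else {
        i0 <- max(which(sub$year < y))
        y0 <- sub$year[i0]; y1 <- sub$year[i0 + 1]
        c0 <- sub$count[i0]; c1 <- sub$count[i0 + 1]
        if (c0 == 0 || c1 == 0) {
          # geometric interpolation degenerates with a zero endpoint;
          # fall back to linear within this interval
          out_counts[j] <- c0 + (c1 - c0) * (y - y0) / (y1 - y0)
        } else {
          out_counts[j] <- c0 * (c1 / c0)^((y - y0) / (y1 - y0))
        }
      }
    }
    tibble::tibble(year = horizon, count = out_counts)
  }

  out <- do.call(rbind, lapply(seq_len(nrow(strata)), function(k) {
    s <- strata[k, ]
    sel <- anchors$sex == s$sex & anchors$age_lower == s$age_lower &
      (anchors$age_upper %in% s$age_upper |
        (is.na(anchors$age_upper) & is.na(s$age_upper)))
    cbind(s[rep(1, length(horizon)), ], interp_one(anchors[sel, ]))
  }))
  tibble::as_tibble(out[c("year", "sex", "age_lower", "age_upper", "count")])
}

#' Reconstruct population denominators from a published "count (prevalence)"
#' table
#'
#' Published prevalence reports often print, per stratum, the number of
#' cases together with the prevalence in percent. The underlying population
#' denominator is then `count / (prevalence / 100)`. Totals rows should not
#' be passed here: they are checksums, not denominator sources.
#'
#' @param report A data frame with columns `sex`, `band` (label, e.g.
#'   "25-34"), `year`, `count` (cases) and `prevalence_pct` (percent,
#'   printed precision).
#' @return A tibble `year`, `sex`, `age_lower`, `age_upper`, `count` where
#'   `count` is the reconstructed denominator (persons). Cells with zero
#'   count and zero prevalence yield `NA` denominators (flagged unknown).
#' @export
#' @examples
#' reconstruct_denominators(tibble::tibble(
#'   sex = "M", band = "25-34", year = 2003,
#'   count = 16995, prevalence_pct = 1.2
#' ))
reconstruct_denominators <- function(report) {
  req <- c("sex", "band", "year", "count", "prevalence_pct")
  if (!all(req %in% names(report))) {
    stop("report must have columns: ", paste(req, collapse = ", "),
      call. = FALSE
    )
  }
  check_sex(report$sex)
  if (any(report$count < 0)) stop("counts must be >= 0", call. = FALSE)
  bad <- report$prevalence_pct == 0 & report$count > 0
  if (any(bad)) {
    stop("prevalence 0 with positive count in stratum/strata: ",
      paste(report$sex[bad], report$band[bad], report$year[bad],
        collapse = "; "
      ),
      call. = FALSE
    )
  }
  bands <- parse_age_band(report$band)
  denom <- ifelse(report$prevalence_pct > 0,
    report$count / (report$prevalence_pct / 100),
    ifelse(report$count == 0, NA_real_, NA_real_)
  )
  tibble::tibble(
    year = report$year, sex = report$sex,
    age_lower = bands$age_lower, age_upper = bands$age_upper,
    count = denom
  )
}

#' Entrants into the youngest model age band
#'
#' Reconciles the youngest band's year-over-year population change with
#' within-band aging-out and deaths: `entrants = N(t+1) - (N(t) - aged_out -
#' deaths)`. Negative balances are floored at zero with a warning (they
#' indicate net out-migration or inconsistent inputs, which the model does
#' not represent).
#'
#' @param pop Population table (`year`, `sex`, `age_lower`, `age_upper`,
#'   `count`) holding at least years `year - 1` and `year`.
#' @param year Calendar year for which entrants (arriving during the cycle
#'   `year - 1` to `year`) are computed.
#' @param aged_out,deaths Named numeric vectors (names "M", "F") of persons
#'   leaving the youngest band during the cycle by aging and death.
#' @return Named numeric vector of entrants per sex.
#' @export
cohort_entry <- function(pop, year,
                         aged_out = c(M = 0, F = 0),
                         deaths = c(M = 0, F = 0)) {
  if (!(year - 1) %in% pop$year) {
    stop("no prior year ", year - 1, " in population table; entrants are ",
      "undefined for the first year of the horizon",
      call. = FALSE
    )
  }
  youngest <- min(pop$age_lower)
  out <- vapply(c("M", "F"), function(s) {
    n0 <- sum(pop$count[pop$year == year - 1 & pop$sex == s &
      pop$age_lower == youngest])
    n1 <- sum(pop$count[pop$year == year & pop$sex == s &
      pop$age_lower == youngest])
    n1 - (n0 - aged_out[[s]] - deaths[[s]])
  }, numeric(1))
  if (any(out < 0)) {
    warning("negative entrant count floored at 0 for sex: ",
      paste(names(out)[out < 0], collapse = ", "),
      call. = FALSE
    )
    out[out < 0] <- 0
  }
  out
}

#' Read/write population tables
#'
#' CSV layout: columns `year`, `sex` ("M"/"F"), `age_lower`, `age_upper`
#' (empty = open-ended band), `count`.
#'
#' @param path File path.
#' @return `read_population_csv()` returns a tibble; `write_population_csv()`
#'   returns `path` invisibly.
#' @export
read_population_csv <- function(path) {
  out <- readr::read_csv(path,
    col_types = readr::cols(
      year = readr::col_integer(), sex = readr::col_character(),
      age_lower = readr::col_integer(), age_upper = readr::col_integer(),
      count = readr::col_double()
    )
  )
  check_sex(out$sex)
  out
}

#' @rdname read_population_csv
#' @param pop Population table.
#' @export
write_population_csv <- function(pop, path) {
  readr::write_csv(pop, path, na = "")
  invisible(path)
}
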