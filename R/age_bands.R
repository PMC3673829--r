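#' Age-band utilities
#'
#' The model runs on closed 10-year age bands from 25 upward plus one
#' open-ended band. Bands are represented throughout by a pair of columns,
#' `age_lower` (integer years, inclusive) and `age_upper` (integer years,
#' exclusive; `NA` for an open-ended band). Labels follow the reporting
#' convention "25-34", ..., "75+".
#'
#' @name age_bands
NULL

#' Core model age bands
#'
#' The six bands used by the projection engine and the standard reports:
#' 25-34, 35-44, 45-54, 55-64, 65-74 and 75+.
#'
#' @return A tibble with columns `age_lower`, `age_upper` (`NA` = open) and
#'   `band` (label).
#' @export
#' @examples
#' age_bands_core()
age_bands_core <- function() {
  tibble::tibble(
    age_lower = c(25L, 35L, 45L, 55L, 65L, 75L),
    age_upper = c(35L, 45L, 55L, 65L, 75L, NA),
    band = c("25-34", "35-44", "45-54", "55-64", "65-74", "75+")
  )
}

#' @rdname age_bands_core
#' @param age_lower,age_upper Integer vectors describing bands; `age_upper`
#'   is exclusive and `NA` marks an open-ended band.
#' @export
format_age_band <- function(age_lower, age_upper) {
  ifelse(is.na(age_upper),
    paste0(age_lower, "+"),
    paste0(age_lower, "-", age_upper - 1L)
  )
}

#' @rdname age_bands_core
#' @param band Character vector of band labels such as `"25-34"` or `"75+"`.
#' @export
parse_age_band <- function(band) {
  band <- trimws(band)
  open <- grepl("\\+$", band)
  lower <- suppressWarnings(as.integer(sub("[-+].*$", "", band)))
  upper <- rep(NA_integer_, length(band))
  closed <- !open & grepl("-", band)
  upper[closed] <- suppressWarnings(
    as.integer(sub("^.*-", "", band[closed]))
  ) + 1L
  bad <- is.na(lower) | (!open & !closed)
  if (any(bad)) {
    stop("Unparseable age band label(s): ",
      paste(unique(band[bad]), collapse = ", "),
      call. = FALSE
    )
  }
  tibble::tibble(age_lower = lower, age_upper = upper)
}

#' Width of an age band in years
#'
#' Open-ended bands are assigned a nominal width (default 10 years), used by
#' the 1/width aging approximation and for locating band midpoints.
#'
#' @inheritParams format_age_band
#' @param open_width Nominal width for open-ended bands.
#' @return Numeric vector of widths.
#' @export
band_width <- function(age_lower, age_upper, open_width = 10) {
  ifelse(is.na(age_upper), open_width, age_upper - age_lower)
}

# Internal: canonical stratum ordering (sex M before F, bands by age_lower).
stratum_order <- function(df) {
  order(match(df$sex, c("M", "F")), df$age_lower)
}

check_sex <- function(sex) {
  if (!all(sex %in% c("M", "F"))) {
    stop("`sex` must be encoded \"M\"/\"F\"; got: ",
      paste(setdiff(unique(sex), c("M", "F")), collapse = ", "),
      call. = FALSE
    )
  }
  invisible(sex)
}
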