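#' Calendar-month index helpers
#'
#' Exposure histories and exam dates are indexed on a continuous integer
#' month scale so that lagging and window arithmetic are plain integer
#' subtraction.  Index 0 corresponds to January 2000; each unit is one
#' calendar month.
#'
#' @param year,month integer calendar year and month (1-12).
#' @param idx integer month index (months since 2000-01).
#' @return `month_index()` returns the integer index; `month_label()` a
#'   `"YYYY-MM"` string; `month_of_year()` the month number 1-12;
#'   `month_season()` a factor with levels winter/spring/summer/autumn.
#' @examples
#' month_index(2003, 1)        # 36
#' month_label(month_index(2004, 6))
#' @export
month_index <- function(year, month) {
  stopifnot(all(month >= 1L), all(month <= 12L))
  as.integer((year - 2000L) * 12L + (month - 1L))
}

#' @rdname month_index
#' @export
month_label <- function(idx) {
  sprintf("%04d-%02d", 2000L + idx %/% 12L, idx %% 12L + 1L)
}

#' @rdname month_index
#' @export
month_of_year <- function(idx) as.integer(idx %% 12L + 1L)

#' @rdname month_index
#' @export
month_year <- function(idx) as.integer(2000L + idx %/% 12L)

season_levels <- c("winter", "spring", "summer", "autumn")

#' @rdname month_index
#' @export
month_season <- function(idx) {
  moy <- month_of_year(idx)
  s <- c("winter", "winter", "spring", "spring", "spring", "summer",
         "summer", "summer", "autumn", "autumn", "autumn", "winter")[moy]
  factor(s, levels = season_levels)
}

parse_month_label <- function(x) {
  m <- regmatches(x, regexec("^([0-9]{4})-([0-9]{2})$", x))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop("malformed month label(s): ", paste(x[bad], collapse = ", "))
  month_index(as.integer(vapply(m, `[`, "", 2L)),
              as.integer(vapply(m, `[`, "", 3L)))
}
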