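#' ISO-8601 week helpers
#'
#' Week-of-year and week-based year under ISO-8601 numbering, as used for
#' weekly mortality series. The week-based year can differ from the calendar
#' year near January 1.
#'
#' @param dates a `Date` vector.
#' @return integer vector.
#' @examples
#' iso_week(as.Date("2015-05-01")) # 18
#' @export
iso_week <- function(dates) as.integer(format(dates, "%V"))

#' @rdname iso_week
#' @export
iso_year <- function(dates) as.integer(format(dates, "%G"))

#' Dates of the warm season
#'
#' All calendar dates whose ISO week falls in `season_weeks` and whose ISO
#' (week-based) year is in `years`. The default range, weeks 18-39, covers
#' approximately May through September.
#'
#' @param years integer vector of ISO years.
#' @param season_weeks inclusive ISO-week range, length 2.
#' @return sorted `Date` vector; every ISO week in range is complete (7 days).
#' @export
season_dates <- function(years, season_weeks = c(18L, 39L)) {
  stopifnot(length(season_weeks) == 2, season_weeks[1] <= season_weeks[2])
  # pad the calendar scan so edge ISO weeks belonging to adjacent years are seen
  all_days <- seq(as.Date(paste0(min(years) - 1, "-12-15")),
                  as.Date(paste0(max(years) + 1, "-01-15")), by = "day")
  keep <- iso_year(all_days) %in% years &
    iso_week(all_days) >= season_weeks[1] & iso_week(all_days) <= season_weeks[2]
  all_days[keep]
}
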