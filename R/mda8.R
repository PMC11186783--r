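#' Daily maximum 8-hour average (MDA8) ozone
#'
#' Computes the regulatory MDA8 metric from an hourly series. Following the
#' EU-directive convention, each calendar day has 24 candidate 8-hour windows,
#' ending at 01:00 through 24:00, so the earliest windows reach back into the
#' previous day. A window contributes if at least 6 of its 8 hours are
#' present; its value is the mean of the present hours. The MDA8 is the
#' maximum over qualifying windows; a day with no qualifying window gets
#' `mda8 = NA` and `valid = FALSE`.
#'
#' `valid` additionally requires the day to pass the >75% hourly-availability
#' rule (at least 19 of 24 hours present; see [availability_filter()]).
#'
#' @param hourly tibble with columns `station_id` (optional), `timestamp`
#'   (POSIXct, hourly) and `value` (ug m-3, `NA` for missing). Duplicate hours
#'   are an error; gaps are treated as missing hours.
#' @return tibble `(station_id, date, mda8, n_valid_hours, valid)`; the
#'   `station_id` column is present only if supplied.
#' @examples
#' h <- tibble::tibble(
#'   timestamp = as.POSIXct("2015-06-01", tz = "UTC") + 3600 * (0:23),
#'   value = 1:24
#' )
#' mda8_series(h) # mda8 = mean(17:24) = 20.5
#' @export
mda8_series <- function(hourly) {
  stopifnot(all(c("timestamp", "value") %in% names(hourly)))
  has_station <- "station_id" %in% names(hourly)
  if (!has_station) hourly$station_id <- "station"
  if (any(!is.na(hourly$value) & hourly$value < 0))
    stop("negative hourly concentration", call. = FALSE)
  parts <- split(hourly, hourly$station_id)
  out <- dplyr::bind_rows(lapply(names(parts), function(sid) {
    res <- mda8_one_station(parts[[sid]])
    res$station_id <- sid
    res
  }))
  if (nrow(out) == 0) {
    out <- tibble::tibble(station_id = character(),
                          date = as.Date(character()), mda8 = numeric(),
                          n_valid_hours = integer(), valid = logical())
  }
  out <- dplyr::select(out, "station_id", "date", "mda8", "n_valid_hours",
                       "valid")
  if (!has_station) out$station_id <- NULL
  dplyr::arrange(out, dplyr::across(dplyr::any_of("station_id")), .data$date)
}

mda8_one_station <- function(df) {
  if (nrow(df) == 0) {
    return(tibble::tibble(date = as.Date(character()), mda8 = numeric(),
                          n_valid_hours = integer(), valid = logical()))
  }
  if (anyDuplicated(df$timestamp))
    stop("duplicate hourly timestamps for a station", call. = FALSE)
  dates <- seq(as.Date(min(df$timestamp), tz = "UTC"),
               as.Date(max(df$timestamp), tz = "UTC"), by = "day")
  full <- as.POSIXct(dates[1], tz = "UTC") +
    3600 * (0:(24 * length(dates) - 1))
  x <- rep(NA_real_, length(full))
  x[match(as.numeric(df$timestamp), as.numeric(full))] <- df$value

  # rolling 8-h windows on a series padded with 7 leading NAs: window ending
  # at position i covers hours i-7..i (reaching into the previous day)
  xp <- c(rep(NA_real_, 7L), x)
  ok <- !is.na(xp)
  cs <- c(0, cumsum(ifelse(ok, xp, 0)))
  cn <- c(0L, cumsum(ok))
  idx <- seq_along(x) + 7L
  wsum <- cs[idx + 1L] - cs[idx - 7L]
  wcnt <- cn[idx + 1L] - cn[idx - 7L]
  wmean <- ifelse(wcnt >= 6L, wsum / wcnt, NA_real_)

  day_of <- rep(seq_along(dates), each = 24L)
  mda8 <- tapply(wmean, day_of, function(v) {
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  })
  n_valid <- tapply(!is.na(x), day_of, sum)
  tibble::tibble(
    date = dates,
    mda8 = as.numeric(mda8),
    n_valid_hours = as.integer(n_valid),
    valid = !is.na(as.numeric(mda8)) &
      availability_filter(as.integer(n_valid))
  )
}

#' Hourly data-availability filter
#'
#' A station-day is usable only when strictly more than 75% of its hourly
#' observations are present: 18 of 24 hours (exactly 75%) fails, 19 passes.
#'
#' @param n_valid_hours integer vector of valid-hour counts, in 0-24.
#' @return logical vector.
#' @export
availability_filter <- function(n_valid_hours) {
  if (any(is.na(n_valid_hours)) || any(n_valid_hours < 0 | n_valid_hours > 24))
    stop("n_valid_hours must be in [0, 24]", call. = FALSE)
  n_valid_hours / 24 > 0.75
}
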