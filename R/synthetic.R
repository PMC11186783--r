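#' Generate a source-tagged MDA8 ozone field
#'
#' Simulates daily MDA8 ozone per grid cell as a latitudinal baseline
#' (increasing southwards), a smooth seasonal bump peaking mid-season, an AR(1)
#' synoptic anomaly shared across the grid, and independent per-cell noise,
#' truncated at zero. The total is split across source tags with the constant
#' shares of `config$source_share_profile`, so per-cell totals equal the sum
#' over tags by construction and the ground-truth apportionment is known.
#'
#' With `expanded = TRUE` the "european" share is further split by source
#' country: the "national" tag becomes the cell's own country id and the
#' remainder is distributed over the other countries with fixed (seeded)
#' weights, as required by [country_matrix()].
#'
#' @param config a [scenario_config()].
#' @param region_map a [generate_region_map()] result; required when
#'   `expanded = TRUE` (the split depends on each cell's country). With
#'   expanded tags, `config$source_tags` must contain "national" and
#'   "european".
#' @param expanded logical; resolve the other-European tag per source country.
#' @return tibble `(day, cell_id, tag, value_ugm3)` — a tagged exposure field.
#' @export
generate_exposure <- function(config, region_map = NULL, expanded = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  if (expanded) {
    if (is.null(region_map))
      stop("expanded tags require a region map", call. = FALSE)
    if (!all(c("national", "european") %in% config$source_tags))
      stop("expanded tags require 'national' and 'european' in source_tags",
           call. = FALSE)
  }
  set.seed(config$rng_seed + 101L)
  grid <- cell_grid(config)
  dates <- season_dates(config$years, config$season_weeks)
  nd <- length(dates)
  nc <- nrow(grid)

  frac <- if (config$n_lat_cells > 1) {
    (grid$row - 1) / (config$n_lat_cells - 1)
  } else rep(1, nc)
  base_cell <- config$baseline_o3_north +
    frac * (config$baseline_o3_south - config$baseline_o3_north)

  # seasonal bump: 0 at season edges, peak mid-season, per ISO year
  yr <- iso_year(dates)
  u <- ave(seq_along(dates), yr,
           FUN = function(i) (seq_along(i) - 1) / max(1L, length(i) - 1L))
  seasonal <- 12 * sin(pi * u)

  # synoptic AR(1) anomaly common to all cells
  eps <- rnorm(nd, 0, 6)
  syn <- numeric(nd)
  phi <- 0.6
  for (t in seq_len(nd)) syn[t] <- if (t == 1L) eps[t] else phi * syn[t - 1L] + eps[t]

  total <- pmax(outer(seasonal + syn, base_cell, `+`) +
                  matrix(rnorm(nd * nc, 0, 3), nd, nc), 0)

  daily <- tibble::tibble(
    day = rep(dates, times = nc),
    cell_id = rep(grid$cell_id, each = nd),
    total = as.vector(total)
  )

  if (!expanded) {
    tags <- config$source_tags
    shares <- config$source_share_profile
    out <- tibble::tibble(
      day = rep(daily$day, times = length(tags)),
      cell_id = rep(daily$cell_id, times = length(tags)),
      tag = rep(tags, each = nrow(daily)),
      value_ugm3 = as.vector(outer(daily$total, shares))
    )
  } else {
    out <- expand_tags(daily, config, region_map)
  }
  dplyr::arrange(out, .data$day, .data$cell_id, .data$tag)
}

# split the aggregate national/european shares into per-country tags
expand_tags <- function(daily, config, region_map) {
  shares <- setNames(config$source_share_profile, config$source_tags)
  countries <- sort(unique(region_map$cells$country_id))
  # fixed country weights for the european split (seeded by the caller)
  w <- setNames(rgamma(length(countries), shape = 2, rate = 1), countries)
  share_map <- dplyr::bind_rows(lapply(countries, function(cty) {
    others <- setdiff(countries, cty)
    ws <- w[others] / sum(w[others])
    tibble::tibble(
      country_id = cty,
      tag = c(cty, others, setdiff(names(shares), c("national", "european"))),
      mult = c(shares[["national"]], shares[["european"]] * ws,
               unname(shares[setdiff(names(shares), c("national", "european"))]))
    )
  }))
  cell_cty <- dplyr::select(region_map$cells, "cell_id", "country_id")
  daily |>
    dplyr::inner_join(cell_cty, by = "cell_id") |>
    dplyr::inner_join(share_map, by = "country_id",
                      relationship = "many-to-many") |>
    dplyr::transmute(.data$day, .data$cell_id, .data$tag,
                     value_ugm3 = .data$total * .data$mult)
}

#' Generate a cell-to-region map with population
#'
#' Partitions the grid into `n_regions` contiguous (raster-order) regions,
#' nests consecutive regions into `n_countries` countries, and draws a
#' log-normal population per cell. Every cell belongs to exactly one region
#' and every region to exactly one country.
#'
#' @param config a [scenario_config()].
#' @return a `region_map`: list with `cells` (tibble `cell_id, row, col,
#'   region_id, country_id, population`), `regions` (tibble `region_id,
#'   country_id, population`), and `total_population`.
#' @export
generate_region_map <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$rng_seed + 202L)
  grid <- cell_grid(config)
  n_cells <- nrow(grid)
  region_idx <- ceiling(seq_len(n_cells) / (n_cells / config$n_regions))
  region_idx <- pmin(region_idx, config$n_regions)
  country_idx <- ceiling(region_idx / (config$n_regions / config$n_countries))
  country_idx <- pmin(country_idx, config$n_countries)
  cells <- grid |>
    dplyr::mutate(
      region_id = sprintf("R%03d", region_idx),
      country_id = sprintf("C%02d", country_idx),
      population = round(rlnorm(n_cells, meanlog = log(2e4), sdlog = 0.8))
    )
  regions <- cells |>
    dplyr::group_by(.data$region_id, .data$country_id) |>
    dplyr::summarise(population = sum(.data$population), .groups = "drop")
  structure(list(cells = cells, regions = regions,
                 total_population = sum(cells$population)),
            class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf("<region_map> %d cells, %d regions, %d countries, population %s\n",
              nrow(x$cells), nrow(x$regions),
              length(unique(x$regions$country_id)),
              format(x$total_population, big.mark = ",")))
  invisible(x)
}

#' Generate weekly all-cause mortality counts
#'
#' Draws independent Poisson death counts per (region, ISO year, ISO week in
#' season) with mean `region population x baseline_weekly_death_rate`,
#' emulating a weekly all-cause mortality series.
#'
#' @param config a [scenario_config()].
#' @param region_map a [generate_region_map()] result.
#' @return tibble `(region_id, iso_year, iso_week, deaths)`.
#' @export
generate_mortality <- function(config, region_map) {
  stopifnot(inherits(config, "scenario_config"),
            inherits(region_map, "region_map"))
  set.seed(config$rng_seed + 303L)
  out <- tidyr::crossing(
    region_id = region_map$regions$region_id,
    iso_year = config$years,
    iso_week = seq(config$season_weeks[1], config$season_weeks[2])
  ) |>
    dplyr::inner_join(dplyr::select(region_map$regions, "region_id",
                                    "population"), by = "region_id") |>
    dplyr::arrange(.data$region_id, .data$iso_year, .data$iso_week)
  out$deaths <- rpois(nrow(out),
                      out$population * config$baseline_weekly_death_rate)
  dplyr::select(out, -"population")
}

#' Generate monitoring stations with hourly observation series
#'
#' Places stations on randomly chosen grid cells, assigns a type label and an
#' altitude (a mix of rural-background and urban-traffic sites, some above
#' 1,000 m so the downstream evaluation filter is exercised), and builds an
#' hourly series per station whose daily MDA8 equals the cell's true total
#' MDA8 plus Gaussian noise of sd `config$obs_noise_sd` (the hourly profile
#' has an 8-hour afternoon plateau at that level, so the maximum 8-h mean
#' reproduces it exactly).
#' Individual hours are masked missing with probability `missing_prob`,
#' exercising the >75% availability rule.
#'
#' @param config a [scenario_config()].
#' @param exposure a tagged exposure field from [generate_exposure()].
#' @param n_stations number of stations.
#' @param missing_prob per-hour missingness probability.
#' @return a `station_set`: list with `stations` (tibble `station_id, cell_id,
#'   type, altitude_m`) and `hourly` (tibble `station_id, timestamp, value`,
#'   UTC, missing hours as `NA`).
#' @export
generate_observations <- function(config, exposure, n_stations = 15L,
                                  missing_prob = 0.03) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$rng_seed + 404L)
  totals <- exposure |>
    dplyr::group_by(.data$day, .data$cell_id) |>
    dplyr::summarise(total = sum(.data$value_ugm3), .groups = "drop")
  cells <- unique(totals$cell_id)
  stations <- tibble::tibble(
    station_id = sprintf("ST%03d", seq_len(n_stations)),
    cell_id = sample(cells, n_stations, replace = n_stations > length(cells)),
    type = sample(c("rural_background", "urban_traffic"), n_stations,
                  replace = TRUE, prob = c(0.85, 0.15)),
    altitude_m = round(runif(n_stations, 0, 1200))
  )
  st_days <- dplyr::inner_join(stations, totals, by = "cell_id",
                               relationship = "many-to-many")
  st_days$obs <- pmax(st_days$total + rnorm(nrow(st_days), 0,
                                            config$obs_noise_sd), 0)
  n <- nrow(st_days)
  # diurnal profile: an 8-h afternoon plateau at the target level, quarter
  # level otherwise, so the day's MDA8 equals the target exactly and windows
  # reaching into the previous evening can never exceed it
  profile <- rep(0.25, 24)
  profile[11:18] <- 1 # hours 10:00-17:00
  hourly <- tibble::tibble(
    station_id = rep(st_days$station_id, each = 24L),
    timestamp = rep(as.POSIXct(st_days$day, tz = "UTC"), each = 24L) +
      3600 * rep(0:23, times = n),
    value = rep(st_days$obs, each = 24L) * rep(profile, times = n)
  )
  hourly$value[runif(nrow(hourly)) < missing_prob] <- NA_real_
  structure(list(stations = stations, hourly = hourly), class = "station_set")
}

#' @export
print.station_set <- function(x, ...) {
  cat(sprintf("<station_set> %d stations (%d rural background < 1000 m), %s hourly records\n",
              nrow(x$stations),
              sum(x$stations$type == "rural_background" & x$stations$altitude_m < 1000),
              format(nrow(x$hourly), big.mark = ",")))
  invisible(x)
}
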