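#' Synthetic scenario configuration
#'
#' Defines the study conditions for the synthetic-data generator: an abstract
#' regular lat-lon lattice (row 1 = northernmost), contiguous regions nested in
#' countries, a warm-season week range, a set of source tags with fixed
#' concentration shares, and the stochastic parameters of the ozone and
#' mortality processes.
#'
#' Defaults emulate the structure of the European study setting at desk scale:
#' a southward-increasing MDA8 baseline spanning 77-130 ug m-3 (the
#' Finland-to-Malta national range), five source categories with the
#' hemispheric ("boundary") tag dominant, warm-season ISO weeks 18-39 for
#' 2015-2017, and a weekly all-cause death rate of 1.8e-4 per person-week
#' (Eurostat scale: ~6.3M warm-season deaths among ~530M people over three
#' 22-week seasons).
#'
#' @param n_lat_cells,n_lon_cells lattice dimensions.
#' @param n_regions number of regions (`>= n_countries`, `<=` number of cells).
#' @param n_countries number of countries regions nest into.
#' @param years integer ISO years to simulate.
#' @param season_weeks inclusive ISO-week range (within 1-53).
#' @param source_tags ordered character vector of tag labels.
#' @param baseline_o3_south,baseline_o3_north southern/northern MDA8 baseline,
#'   ug m-3; south must be >= north (latitudinal gradient).
#' @param source_share_profile per-tag concentration fractions, >= 0, summing
#'   to 1 (within 1e-12).
#' @param obs_noise_sd sd of station observation noise, ug m-3.
#' @param baseline_weekly_death_rate deaths per person-week.
#' @param rng_seed integer seed; identical configs give byte-identical data.
#' @return a `scenario_config` list.
#' @examples
#' cfg <- scenario_config(n_lat_cells = 3, n_lon_cells = 3, n_regions = 3,
#'                        n_countries = 2, years = 2015)
#' @export
scenario_config <- function(n_lat_cells = 12L,
                            n_lon_cells = 12L,
                            n_regions = 36L,
                            n_countries = 6L,
                            years = 2015:2017,
                            season_weeks = c(18L, 39L),
                            source_tags = c("national", "european",
                                            "other_domain", "maritime",
                                            "boundary"),
                            baseline_o3_south = 130,
                            baseline_o3_north = 77,
                            source_share_profile = c(0.117, 0.209, 0.035,
                                                     0.072, 0.567),
                            obs_noise_sd = 10,
                            baseline_weekly_death_rate = 1.8e-4,
                            rng_seed = 1L) {
  cfg <- list(
    n_lat_cells = as.integer(n_lat_cells),
    n_lon_cells = as.integer(n_lon_cells),
    n_regions = as.integer(n_regions),
    n_countries = as.integer(n_countries),
    years = as.integer(years),
    season_weeks = as.integer(season_weeks),
    source_tags = as.character(source_tags),
    baseline_o3_south = baseline_o3_south,
    baseline_o3_north = baseline_o3_north,
    source_share_profile = as.numeric(source_share_profile),
    obs_noise_sd = obs_noise_sd,
    baseline_weekly_death_rate = baseline_weekly_death_rate,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "scenario_config"
  validate_scenario_config(cfg)
}

validate_scenario_config <- function(cfg) {
  n_cells <- cfg$n_lat_cells * cfg$n_lon_cells
  if (cfg$n_lat_cells < 1 || cfg$n_lon_cells < 1)
    stop("configuration error: lattice dimensions must be >= 1", call. = FALSE)
  if (any(cfg$source_share_profile < 0))
    stop("configuration error: source_share_profile entries must be >= 0",
         call. = FALSE)
  if (abs(sum(cfg$source_share_profile) - 1) > 1e-12)
    stop("configuration error: source_share_profile must sum to 1",
         call. = FALSE)
  if (length(cfg$source_share_profile) != length(cfg$source_tags))
    stop("configuration error: one share per source tag required",
         call. = FALSE)
  if (cfg$baseline_o3_south < cfg$baseline_o3_north)
    stop("configuration error: baseline_o3_south must be >= baseline_o3_north",
         call. = FALSE)
  if (length(cfg$season_weeks) != 2 || any(cfg$season_weeks < 1) ||
      any(cfg$season_weeks > 53) || cfg$season_weeks[1] > cfg$season_weeks[2])
    stop("configuration error: season_weeks must be an increasing range within 1-53",
         call. = FALSE)
  if (cfg$n_regions < cfg$n_countries)
    stop("configuration error: n_regions must be >= n_countries", call. = FALSE)
  if (cfg$n_regions > n_cells)
    stop("configuration error: n_regions exceeds number of grid cells",
         call. = FALSE)
  if (cfg$obs_noise_sd < 0 || cfg$baseline_weekly_death_rate < 0)
    stop("configuration error: noise sd and death rate must be >= 0",
         call. = FALSE)
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  cat(sprintf("  grid: %d x %d (%d cells), %d regions in %d countries\n",
              x$n_lat_cells, x$n_lon_cells, x$n_lat_cells * x$n_lon_cells,
              x$n_regions, x$n_countries))
  cat(sprintf("  years %s, ISO weeks %d-%d\n",
              paste(range(x$years), collapse = "-"),
              x$season_weeks[1], x$season_weeks[2]))
  cat(sprintf("  tags: %s\n  shares: %s\n",
              paste(x$source_tags, collapse = ", "),
              paste(format(x$source_share_profile), collapse = ", ")))
  invisible(x)
}

#' Grid-cell index of a scenario
#'
#' @param config a [scenario_config()].
#' @return tibble with `cell_id`, `row` (1 = northernmost), `col`.
#' @export
cell_grid <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  tibble::tibble(
    cell_id = seq_len(config$n_lat_cells * config$n_lon_cells),
    row = rep(seq_len(config$n_lat_cells), each = config$n_lon_cells),
    col = rep(seq_len(config$n_lon_cells), times = config$n_lat_cells)
  )
}
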