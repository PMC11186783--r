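#' Validate a tagged exposure field
#'
#' Checks the long-format exposure contract: required columns, no negative
#' concentrations, no duplicated (day, cell, tag) rows. When rows with
#' `tag == "total"` are present they are checked against the sum of the other
#' tags (1e-6 relative) and removed.
#'
#' @param exposure tibble `(day, cell_id, tag, value_ugm3)`.
#' @return the validated field (total rows dropped), invisibly usable.
#' @export
validate_exposure <- function(exposure) {
  req <- c("day", "cell_id", "tag", "value_ugm3")
  miss <- setdiff(req, names(exposure))
  if (length(miss) > 0)
    stop("exposure load error: missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(is.na(exposure$value_ugm3) | exposure$value_ugm3 < 0)
  if (length(bad) > 0)
    stop(sprintf("exposure load error: negative or missing concentration at row %d",
                 bad[1]), call. = FALSE)
  if (anyDuplicated(exposure[c("day", "cell_id", "tag")]) > 0)
    stop("exposure load error: duplicated (day, cell_id, tag) rows",
         call. = FALSE)
  if (any(exposure$tag == "total")) {
    tot <- dplyr::filter(exposure, .data$tag == "total")
    parts <- exposure |>
      dplyr::filter(.data$tag != "total") |>
      dplyr::group_by(.data$day, .data$cell_id) |>
      dplyr::summarise(s = sum(.data$value_ugm3), .groups = "drop")
    chk <- dplyr::inner_join(tot, parts, by = c("day", "cell_id"))
    rel <- abs(chk$s - chk$value_ugm3) / pmax(abs(chk$value_ugm3), 1e-12)
    if (nrow(chk) < nrow(tot) || any(rel > 1e-6)) {
      bad_row <- if (any(rel > 1e-6)) which(rel > 1e-6)[1] else NA
      stop(sprintf("exposure load error: tag sum mismatch (day %s, cell %s)",
                   chk$day[bad_row], chk$cell_id[bad_row]), call. = FALSE)
    }
    exposure <- dplyr::filter(exposure, .data$tag != "total")
  }
  exposure
}

#' Read / write a tagged exposure field
#'
#' Long-format CSV with fixed columns `day, cell_id, tag, value_ugm3`.
#' Reading validates the field (see [validate_exposure()]); an optional
#' `tag == "total"` set of rows is additivity-checked on load and dropped.
#'
#' @param path CSV file path.
#' @return [read_exposure()]: the validated exposure tibble.
#' @export
read_exposure <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         day = readr::col_date(),
                         tag = readr::col_character(),
                         value_ugm3 = readr::col_double()
                       ))
  validate_exposure(tibble::as_tibble(x))
}

#' @rdname read_exposure
#' @param exposure exposure tibble.
#' @export
write_exposure <- function(exposure, path) {
  readr::write_csv(validate_exposure(exposure), path)
  invisible(path)
}

#' Build a region map from a cell table
#'
#' Assembles and validates the `region_map` structure from a per-cell table:
#' each cell in exactly one region, each region in exactly one country,
#' populations non-negative; region and total populations are derived.
#'
#' @param cells tibble with `cell_id, region_id, country_id, population`.
#' @return a `region_map`.
#' @export
region_map <- function(cells) {
  cells <- tibble::as_tibble(cells)
  req <- c("cell_id", "region_id", "country_id", "population")
  miss <- setdiff(req, names(cells))
  if (length(miss) > 0)
    stop("region map load error: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(cells$population < 0))
    stop("region map load error: negative population", call. = FALSE)
  if (anyDuplicated(cells$cell_id) > 0)
    stop("region map load error: a cell maps to more than one region",
         call. = FALSE)
  r2c <- dplyr::distinct(cells, .data$region_id, .data$country_id)
  if (anyDuplicated(r2c$region_id) > 0)
    stop("region map load error: a region maps to more than one country",
         call. = FALSE)
  regions <- cells |>
    dplyr::group_by(.data$region_id, .data$country_id) |>
    dplyr::summarise(population = sum(.data$population), .groups = "drop")
  structure(list(cells = cells, regions = regions,
                 total_population = sum(cells$population)),
            class = "region_map")
}

#' Read / write a region map
#'
#' CSV with columns `cell_id, region_id, country_id, population` (and
#' optionally `row`, `col`); reconstructs the `region_map` structure with
#' region and total populations via [region_map()].
#'
#' @param path CSV file path.
#' @return [read_region_map()]: a `region_map`.
#' @export
read_region_map <- function(path) {
  region_map(readr::read_csv(path, show_col_types = FALSE))
}

#' @rdname read_region_map
#' @param region_map a `region_map`.
#' @export
write_region_map <- function(region_map, path) {
  readr::write_csv(region_map$cells, path)
  invisible(path)
}

#' Read / write a weekly mortality series
#'
#' CSV with columns `region_id, iso_year, iso_week, deaths` (non-negative
#' integer counts).
#'
#' @param path CSV file path.
#' @return [read_mortality()]: mortality tibble.
#' @export
read_mortality <- function(path) {
  x <- tibble::as_tibble(readr::read_csv(path, show_col_types = FALSE))
  req <- c("region_id", "iso_year", "iso_week", "deaths")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0)
    stop("mortality load error: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(x$deaths < 0) || any(x$deaths != round(x$deaths)))
    stop("mortality load error: deaths must be non-negative integers",
         call. = FALSE)
  x
}

#' @rdname read_mortality
#' @param mortality mortality tibble.
#' @export
write_mortality <- function(mortality, path) {
  readr::write_csv(mortality, path)
  invisible(path)
}

#' Write a synthetic scenario to disk
#'
#' Generates all pipeline inputs for a scenario and writes them as the
#' package's canonical CSV formats: `exposure.csv`, `regions.csv`,
#' `mortality.csv`, `stations.csv` and `hourly.csv`.
#'
#' @param config a [scenario_config()].
#' @param outdir output directory (created if needed).
#' @param n_stations,missing_prob passed to [generate_observations()].
#' @return named list of file paths, invisibly.
#' @export
simulate_scenario <- function(config, outdir, n_stations = 15L,
                              missing_prob = 0.03) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  rmap <- generate_region_map(config)
  expo <- generate_exposure(config)
  mort <- generate_mortality(config, rmap)
  obs <- generate_observations(config, expo, n_stations, missing_prob)
  paths <- list(
    exposure = file.path(outdir, "exposure.csv"),
    regions = file.path(outdir, "regions.csv"),
    mortality = file.path(outdir, "mortality.csv"),
    stations = file.path(outdir, "stations.csv"),
    hourly = file.path(outdir, "hourly.csv")
  )
  write_exposure(expo, paths$exposure)
  write_region_map(rmap, paths$regions)
  write_mortality(mort, paths$mortality)
  readr::write_csv(obs$stations, paths$stations)
  readr::write_csv(obs$hourly, paths$hourly)
  invisible(paths)
}

#' Read a declarative run configuration
#'
#' YAML file with input paths (`exposure`, `regions`, `mortality`, optionally
#' `stations`, `hourly`), exposure-response coefficients (`beta`, `beta_low`,
#' `beta_high`), optional `threshold` and `threshold_mode`, `rms_u`, and
#' `outdir`.
#'
#' @param path YAML file.
#' @return a named list (class `run_config`).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (p in c("exposure", "regions", "mortality")) {
    if (is.null(cfg[[p]])) stop("run config: missing input path '", p, "'",
                                call. = FALSE)
    if (!file.exists(cfg[[p]])) stop("run config: file not found: ",
                                     cfg[[p]], call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Run the full burden (and optional evaluation) pipeline
#'
#' Binds the modules end to end: load (or accept in-memory) inputs, run the
#' health-impact assessment with eCI propagation and optional threshold
#' sensitivity, evaluate modelled MDA8 against stations when observations are
#' supplied, and write the report tables (per-region tagged burden, country
#' summary, national:imported ratios, evaluation report) to `outdir`. Deaths
#' are rounded to integers and rates to one decimal only in the written
#' reports.
#'
#' @param exposure exposure tibble or CSV path.
#' @param regions `region_map` or CSV path.
#' @param mortality mortality tibble or CSV path.
#' @param beta a [beta_er()].
#' @param threshold,threshold_mode see [hia_burden()].
#' @param observations optional `station_set` (see
#'   [generate_observations()]) or list with `stations` and `hourly` tibbles.
#' @param rms_u measurement uncertainty for [evaluate_stations()].
#' @param outdir optional directory for report CSVs.
#' @param quiet suppress log messages.
#' @return list with `burden` (a `burden_result`), `evaluation` (an
#'   `eval_report` or `NULL`) and `files` (written paths).
#' @export
run_pipeline <- function(exposure, regions, mortality, beta = beta_er(),
                         threshold = NULL,
                         threshold_mode = c("exclude", "zero"),
                         observations = NULL, rms_u = 10,
                         outdir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  if (is.character(exposure)) exposure <- read_exposure(exposure)
  if (is.character(regions)) regions <- read_region_map(regions)
  if (is.character(mortality)) mortality <- read_mortality(mortality)
  say("[hia] %d exposure rows, %d regions, %d mortality records",
      nrow(exposure), nrow(regions$regions), nrow(mortality))

  burden <- hia_burden(exposure, regions, mortality, beta = beta,
                       threshold = threshold,
                       threshold_mode = threshold_mode, quiet = quiet)
  say("[hia] done in %.1f s (dropped: %d partial weeks, %d sub-threshold cell-days, %d unmatched region-weeks)",
      as.numeric(difftime(Sys.time(), t0, units = "secs")),
      burden$dropped$partial_weeks, burden$dropped$sub_threshold_days,
      burden$dropped$unmatched_region_weeks)

  evaluation <- NULL
  if (!is.null(observations)) {
    obs_daily <- mda8_series(observations$hourly)
    model_daily <- station_model_series(exposure, observations$stations)
    evaluation <- evaluate_stations(model_daily, obs_daily,
                                    observations$stations, rms_u = rms_u)
    say("[evaluation] %d stations, MQI objective %s",
        nrow(evaluation$stations),
        if (evaluation$objective_met) "met" else "not met")
  }

  files <- list()
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    region_tab <- seasonal_totals(burden, by = c("region_id", "iso_year",
                                                 "tag")) |>
      dplyr::mutate(dplyr::across(dplyr::all_of(c("an", "an_low", "an_high")),
                                  ~ round(.x)))
    country_tab <- seasonal_totals(burden, by = c("country_id", "tag")) |>
      dplyr::mutate(dplyr::across(dplyr::all_of(c("an", "an_low", "an_high")),
                                  ~ round(.x)))
    ratio_tab <- national_imported_ratio(burden) |>
      dplyr::mutate(ratio = round(.data$ratio, 2))
    files$region_burden <- file.path(outdir, "burden_by_region.csv")
    files$country_summary <- file.path(outdir, "burden_by_country.csv")
    files$ratio <- file.path(outdir, "national_imported_ratio.csv")
    readr::write_csv(region_tab, files$region_burden)
    readr::write_csv(country_tab, files$country_summary)
    readr::write_csv(ratio_tab, files$ratio)
    if (!is.null(evaluation)) {
      files$evaluation <- file.path(outdir, "evaluation_stations.csv")
      readr::write_csv(evaluation$stations, files$evaluation)
    }
    say("[report] wrote %d table(s) to %s", length(files), outdir)
  }
  list(burden = burden, evaluation = evaluation, files = files)
}
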