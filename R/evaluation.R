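#' Filter stations for model evaluation
#'
#' Keeps stations whose spatial representativeness matches a regional model:
#' the configured type label (rural background by default) at altitude
#' strictly below `max_altitude_m` (999 m is kept, 1,000 m is dropped).
#'
#' @param stations tibble with `station_id`, `type`, `altitude_m`.
#' @param type type label to keep.
#' @param max_altitude_m exclusive altitude cut, metres above sea level.
#' @return filtered station tibble; an empty result triggers a message.
#' @export
filter_stations <- function(stations, type = "rural_background",
                            max_altitude_m = 1000) {
  stopifnot(all(c("station_id", "type", "altitude_m") %in% names(stations)))
  if (any(!is.finite(stations$altitude_m)))
    stop("station altitude must be finite", call. = FALSE)
  out <- stations[stations$type == type &
                    stations$altitude_m < max_altitude_m, , drop = FALSE]
  if (nrow(out) == 0)
    message("no stations left after type/altitude filtering")
  out
}

#' Model-skill statistics for a paired daily series
#'
#' Classical evaluation metrics between modelled (M) and observed (O) values:
#' `rmse = sqrt(mean((M-O)^2))`, `nmb = 100 * sum(M-O) / sum(O)` (%),
#' `nrmse = 100 * rmse / mean(O)` (%), and the Pearson correlation.
#'
#' @param model,obs paired numeric vectors (valid days only).
#' @return list with `r`, `nmb`, `nrmse`, `rmse`, `n`.
#' @export
skill_stats <- function(model, obs) {
  stopifnot(length(model) == length(obs))
  ok <- !is.na(model) & !is.na(obs)
  model <- model[ok]; obs <- obs[ok]
  if (length(obs) < 2)
    stop("at least 2 paired days are required", call. = FALSE)
  rmse <- sqrt(mean((model - obs)^2))
  r <- if (sd(obs) > 0 && sd(model) > 0) cor(model, obs) else NA_real_
  list(
    r = r,
    nmb = 100 * sum(model - obs) / sum(obs),
    nrmse = 100 * rmse / mean(obs),
    rmse = rmse,
    n = length(obs)
  )
}

#' Modelling quality indicator (MQI)
#'
#' `MQI = rmse / (beta_mq * rms_u)`, with `beta_mq = 2` allowing the
#' model-observation difference to be twice the measurement uncertainty
#' `rms_u`. `MQI <= 1` marks an acceptable model error at a station.
#'
#' @param rmse root-mean-square model error, ug m-3.
#' @param rms_u root-mean-square measurement uncertainty, ug m-3, > 0.
#' @param beta_mq uncertainty expansion factor.
#' @return the indicator (unitless, >= 0).
#' @export
mqi <- function(rmse, rms_u, beta_mq = 2) {
  if (any(rms_u <= 0)) stop("rms_u must be > 0", call. = FALSE)
  rmse / (beta_mq * rms_u)
}

#' Modelling quality objective over a station network
#'
#' The model meets the quality objective when at least 90% of evaluated
#' stations have `MQI <= 1` (the boundary is inclusive on both counts).
#'
#' @param mqi_values per-station MQI values.
#' @return list with `fraction_passing` and `met`.
#' @export
quality_objective <- function(mqi_values) {
  if (length(mqi_values) == 0)
    stop("at least one evaluated station is required", call. = FALSE)
  frac <- mean(mqi_values <= 1)
  list(fraction_passing = frac, met = frac >= 0.90)
}

#' Evaluate modelled MDA8 against station observations
#'
#' End-to-end evaluation: filters stations (rural background below 1,000 m),
#' keeps only station-days where both the observed MDA8 is valid (availability
#' rule included) and the model value is present, computes per-station skill
#' statistics and MQI, and checks the 90% quality objective. Stations with
#' fewer than 2 paired days are excluded with a message.
#'
#' @param model_daily tibble `(station_id, date, model)` of modelled MDA8.
#' @param obs_daily tibble `(station_id, date, mda8, valid)` from
#'   [mda8_series()].
#' @param stations station metadata tibble (`station_id`, `type`,
#'   `altitude_m`).
#' @param rms_u measurement uncertainty: a positive scalar (ug m-3), or a
#'   function of the observed values returning the per-station rms
#'   uncertainty.
#' @param beta_mq MQI expansion factor.
#' @return an `eval_report`: list with `stations` (per-station tibble of `n`,
#'   `r`, `nmb`, `nrmse`, `rmse`, `mqi`, `passes`), `pooled` (across-station
#'   mean and sd of each metric), `fraction_passing`, `objective_met`.
#' @export
evaluate_stations <- function(model_daily, obs_daily, stations,
                              rms_u = 10, beta_mq = 2) {
  kept <- filter_stations(stations)
  paired <- obs_daily |>
    dplyr::filter(.data$valid, .data$station_id %in% kept$station_id) |>
    dplyr::inner_join(model_daily, by = c("station_id", "date")) |>
    dplyr::filter(!is.na(.data$model), !is.na(.data$mda8))
  counts <- dplyr::count(paired, .data$station_id)
  thin <- counts$station_id[counts$n < 2]
  if (length(thin) > 0)
    message(sprintf("excluding %d station(s) with fewer than 2 paired days",
                    length(thin)))
  paired <- dplyr::filter(paired, !.data$station_id %in% thin)
  if (nrow(paired) == 0)
    stop("no paired station-days available for evaluation", call. = FALSE)

  per_station <- paired |>
    dplyr::group_by(.data$station_id) |>
    dplyr::group_modify(function(d, key) {
      s <- skill_stats(d$model, d$mda8)
      u <- if (is.function(rms_u)) rms_u(d$mda8) else rms_u
      q <- mqi(s$rmse, u, beta_mq)
      tibble::tibble(n = s$n, r = s$r, nmb = s$nmb, nrmse = s$nrmse,
                     rmse = s$rmse, rms_u = u, mqi = q, passes = q <= 1)
    }) |>
    dplyr::ungroup()
  obj <- quality_objective(per_station$mqi)
  pooled <- per_station |>
    dplyr::summarise(dplyr::across(dplyr::all_of(c("r", "nmb", "nrmse",
                                                   "rmse", "mqi")),
                                   list(mean = mean, sd = sd)))
  structure(list(stations = per_station, pooled = pooled,
                 fraction_passing = obj$fraction_passing,
                 objective_met = obj$met),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d stations\n", nrow(x$stations)))
  cat(sprintf("  Pearson r %.2f +/- %.2f, NMB %.2f +/- %.2f%%, NRMSE %.2f +/- %.2f%%\n",
              x$pooled$r_mean, x$pooled$r_sd, x$pooled$nmb_mean,
              x$pooled$nmb_sd, x$pooled$nrmse_mean, x$pooled$nrmse_sd))
  cat(sprintf("  MQI <= 1 at %.0f%% of stations — quality objective %s\n",
              100 * x$fraction_passing,
              if (x$objective_met) "met" else "NOT met"))
  invisible(x)
}

#' Modelled daily MDA8 at station locations
#'
#' Extracts the total (sum over tags) MDA8 series of each station's grid cell
#' from a tagged exposure field, for pairing with observations.
#'
#' @param exposure tibble `(day, cell_id, tag, value_ugm3)`.
#' @param stations tibble with `station_id`, `cell_id`.
#' @return tibble `(station_id, date, model)`.
#' @export
station_model_series <- function(exposure, stations) {
  exposure |>
    dplyr::group_by(.data$day, .data$cell_id) |>
    dplyr::summarise(model = sum(.data$value_ugm3), .groups = "drop") |>
    dplyr::inner_join(dplyr::select(stations, "station_id", "cell_id"),
                      by = "cell_id", relationship = "many-to-many") |>
    dplyr::transmute(.data$station_id, date = .data$day, .data$model)
}
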