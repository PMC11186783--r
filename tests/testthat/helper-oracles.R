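# Brute-force oracles and small fixture factories shared across tests.

# Small, fast scenario: 4x4 grid, 4 regions in 2 countries, one year,
# four warm-season weeks.
tiny_config <- function(seed = 1L, ...) {
  args <- list(
    n_lat_cells = 4L, n_lon_cells = 4L, n_regions = 4L, n_countries = 2L,
    years = 2015L, season_weeks = c(18L, 21L), rng_seed = seed
  )
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(scenario_config, args)
}

# MDA8 by explicit enumeration: 24 windows per day, window i covering
# positions i..i+7 of c(previous 7 hours, day's 24 hours), valid with >= 6
# present hours.
brute_mda8 <- function(hours24, prev7 = rep(NA_real_, 7)) {
  x <- c(prev7, hours24)
  best <- NA_real_
  for (i in 1:24) {
    w <- x[i:(i + 7)]
    if (sum(!is.na(w)) >= 6) {
      m <- mean(w, na.rm = TRUE)
      if (is.na(best) || m > best) best <- m
    }
  }
  best
}

# population-weighted regional AF by explicit per-cell loops
brute_popweight <- function(af_cw, rmap) {
  out <- list()
  for (r in unique(rmap$cells$region_id)) {
    cells_r <- rmap$cells[rmap$cells$region_id == r, ]
    sub <- af_cw[af_cw$cell_id %in% cells_r$cell_id, ]
    for (yw in unique(paste(sub$iso_year, sub$iso_week))) {
      s <- sub[paste(sub$iso_year, sub$iso_week) == yw, ]
      num <- 0; den <- 0
      for (k in seq_len(nrow(s))) {
        p <- cells_r$population[cells_r$cell_id == s$cell_id[k]]
        num <- num + p * s$af[k]
        den <- den + p
      }
      out[[length(out) + 1]] <- data.frame(
        region_id = r, iso_year = s$iso_year[1], iso_week = s$iso_week[1],
        af = num / den
      )
    }
  }
  do.call(rbind, out)
}

# hand-rolled region map: two regions in two countries on a 1x2 grid
two_cell_map <- function(pop = c(1, 3)) {
  region_map(tibble::tibble(
    cell_id = 1:2,
    region_id = c("R001", "R002"),
    country_id = c("C01", "C02"),
    population = pop
  ))
}

# constant-share exposure over given days/cells, summing to `total`
constant_share_exposure <- function(days, cell_ids, tags, shares, total = 100) {
  g <- expand.grid(day = days, cell_id = cell_ids, tag = tags,
                   stringsAsFactors = FALSE)
  g$value_ugm3 <- total * shares[match(g$tag, tags)]
  tibble::as_tibble(g)
}
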