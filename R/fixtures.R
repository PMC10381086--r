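# Scenario fixtures: fully seeded, programmatically generated test inputs
# in the same formats the forcing module consumes.

#' Generate a named test scenario
#'
#' Every scenario is fully determined by (name, overrides, seed); with a
#' fixed seed the outputs (including any files written) are byte-identical
#' across calls.
#'
#' Scenarios:
#' \describe{
#'   \item{soi_default}{the default synthetic South-Orkney-style season.}
#'   \item{all_ice}{same season but ice-covered on all 166 days.}
#'   \item{zero_food}{chlorophyll identically zero.}
#'   \item{unlimited_food}{default forcing plus a config running the DEB
#'     models with functional response fixed at 1.}
#'   \item{toy_grid}{writes two years of daily 0.05-degree gridded CSVs
#'     (sst and chl) with known per-day means for climatology-reader
#'     tests; returns the file paths and the true day-of-year means.}
#'   \item{toy_grid_forcing}{a small uniform-forcing \code{grid_forcing}
#'     (optionally with one all-ice cell) for engine tests.}
#' }
#'
#' @param scenario scenario name.
#' @param overrides named list of \code{soi_forcing_config} or scenario
#'   parameter overrides.
#' @param seed integer seed.
#' @param dir directory for file-emitting scenarios (default tempdir).
#' @return scenario-dependent (see above).
#' @export
make_fixture <- function(scenario, overrides = list(), seed = 1,
                         dir = tempdir()) {
  soi_cfg <- function(extra = list()) {
    do.call(soi_forcing_config, utils::modifyList(extra, overrides))
  }
  switch(scenario,
    soi_default = synthetic_soi_forcing(soi_cfg(), seed = seed),
    all_ice = synthetic_soi_forcing(soi_cfg(list(ice = TRUE)), seed = seed),
    zero_food = synthetic_soi_forcing(
      soi_cfg(list(chl_base = 0, bloom_amplitude = 0)), seed = seed),
    unlimited_food = list(
      forcing = synthetic_soi_forcing(soi_cfg(), seed = seed),
      config = simulation_config(unlimited_food = TRUE)),
    toy_grid = make_toy_grid_files(overrides, seed, dir),
    toy_grid_forcing = make_toy_grid_forcing(overrides, seed),
    stop("unknown scenario '", scenario, "'"))
}

# Two years of daily values on a fine grid; per-cell values depend only on
# day of year plus a seeded year offset so the true climatology is known.
make_toy_grid_files <- function(overrides, seed, dir) {
  p <- utils::modifyList(list(
    lon = seq(-45.225, -45.025, by = 0.05),
    lat = seq(-60.225, -60.025, by = 0.05),
    years = c(2003, 2005),  # non-leap years
    sst_fun = function(doy) -1 + 2 * sin(2 * pi * doy / 365),
    chl_fun = function(doy) 0.5 + 0.4 * cos(2 * pi * doy / 365),
    year_offset = c(-0.1, 0.1)), overrides)
  cells <- expand.grid(lon = p$lon, lat = p$lat)
  paths <- character(0)
  truth <- list()
  for (var in c("sst", "chl")) {
    fun <- if (var == "sst") p$sst_fun else p$chl_fun
    rows <- list()
    for (yi in seq_along(p$years)) {
      dates <- seq(as.Date(sprintf("%d-01-01", p$years[yi])),
                   as.Date(sprintf("%d-12-31", p$years[yi])), by = "day")
      doy <- as.POSIXlt(dates)$yday + 1
      base <- fun(doy) + p$year_offset[yi]
      rows[[yi]] <- data.frame(
        lon = rep(cells$lon, each = length(dates)),
        lat = rep(cells$lat, each = length(dates)),
        date = rep(as.character(dates), nrow(cells)),
        value = rep(base, nrow(cells)))
    }
    df <- do.call(rbind, rows)
    path <- file.path(dir, sprintf("toy_%s_seed%d.csv", var, seed))
    utils::write.csv(df, path, row.names = FALSE)
    paths[var] <- path
    truth[[var]] <- fun(1:365) + mean(p$year_offset)
  }
  list(paths = paths, truth = truth, params = p)
}

make_toy_grid_forcing <- function(overrides, seed) {
  p <- utils::modifyList(list(
    lon = c(-45.125, -44.875, -44.625),
    lat = rep(-60.125, 3),
    start = "2009-11-01", end = "2010-04-15",
    sst = 0.5, chl = 1.0, ice_cell = NA), overrides)
  dates <- seq(as.Date(p$start), as.Date(p$end), by = "day")
  ncell <- length(p$lon)
  sst <- matrix(p$sst, ncell, length(dates))
  chl <- matrix(p$chl, ncell, length(dates))
  ice <- matrix(FALSE, ncell, length(dates))
  if (!is.na(p$ice_cell)) ice[p$ice_cell, ] <- TRUE
  grid_forcing_from_arrays(p$lon, p$lat, dates, sst, chl, ice = ice)
}
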