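# Gridded forcing: climatology ingestion from plain-text gridded tables,
# block-mean downsampling, day-of-year averaging and the polar-front mask.

#' Load a gridded daily climatology from a plain-text table
#'
#' Reads a long-format gridded table (columns \code{lon, lat, date, value},
#' optionally \code{units}), block-means the values onto a regular grid of
#' the requested resolution, and averages over years into a 365-bin
#' day-of-year climatology (29 February observations are folded into day
#' 59). Per-cell means use the available observations only; cells/days with
#' fewer than \code{min_samples} observations are flagged, not dropped. An
#' optional centred rolling mean smooths the climatology along the
#' day-of-year axis (with wraparound).
#'
#' @param path CSV file with columns \code{lon}, \code{lat}, \code{date},
#'   \code{value} and optionally \code{units}.
#' @param variable name of the variable ("sst" or "chl", say); stored as
#'   metadata.
#' @param resolution target grid resolution in degrees (default 0.25).
#' @param units expected units string; if the file carries a \code{units}
#'   column that disagrees, loading fails.
#' @param window odd window (days) for the rolling-mean smoothing of the
#'   climatology; \code{NULL} or 1 disables smoothing.
#' @param min_samples minimum observations per cell-day before flagging.
#' @return an object of class \code{grid_climatology}: cell table, day-of-
#'   year axis, value matrix (cells x 365), sample counts and flags.
#' @export
load_climatology <- function(path, variable, resolution = 0.25,
                             units = NULL, window = 15, min_samples = 1) {
  df <- utils::read.csv(path)
  need <- c("lon", "lat", "date", "value")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("gridded table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!is.null(units) && "units" %in% names(df)) {
    got <- unique(df$units)
    if (!all(got == units))
      stop(sprintf("unit mismatch: expected '%s', file has '%s'",
                   units, paste(unique(got), collapse = ",")))
  }
  dates <- as.Date(df$date)
  if (any(is.na(dates))) stop("unparseable entries on the time axis")
  # block-mean downsampling onto cell centres of the target resolution
  cell_lon <- floor(df$lon / resolution) * resolution + resolution / 2
  cell_lat <- floor(df$lat / resolution) * resolution + resolution / 2
  doy <- day_of_year_365(dates)
  key <- paste(cell_lon, cell_lat, sep = "/")
  # mean per (cell, date) first (block mean), then per (cell, doy) over years
  agg <- stats::aggregate(df$value,
                          by = list(key = key, date = as.numeric(dates), doy = doy),
                          FUN = mean, na.rm = TRUE)
  clim <- stats::aggregate(agg$x, by = list(key = agg$key, doy = agg$doy),
                           FUN = mean, na.rm = TRUE)
  cnt <- stats::aggregate(agg$x, by = list(key = agg$key, doy = agg$doy),
                          FUN = function(v) sum(!is.na(v)))
  cells <- unique(data.frame(key = key, lon = cell_lon, lat = cell_lat,
                             stringsAsFactors = FALSE))
  cells <- cells[order(cells$lat, cells$lon), ]
  rownames(cells) <- NULL
  ncell <- nrow(cells)
  values <- matrix(NA_real_, ncell, 365)
  nsamp <- matrix(0L, ncell, 365)
  ci <- match(clim$key, cells$key)
  values[cbind(ci, clim$doy)] <- clim$x
  nsamp[cbind(match(cnt$key, cells$key), cnt$doy)] <- cnt$x
  if (!is.null(window) && window > 1) {
    k <- (window - 1) / 2
    values <- t(apply(values, 1, function(v) {
      ext <- c(v[(365 - k + 1):365], v, v[1:k])  # circular wrap
      rolling_mean_smooth(ext, window)[(k + 1):(k + 365)]
    }))
  }
  structure(list(variable = variable, resolution = resolution,
                 cells = cells[, c("lon", "lat")], doy = 1:365,
                 values = values, n_samples = nsamp,
                 flagged = nsamp < min_samples & nsamp > 0,
                 units = units),
            class = "grid_climatology")
}

# 365-day calendar convention: 29 Feb folds into day 59.
day_of_year_365 <- function(dates) {
  lt <- as.POSIXlt(dates)
  doy <- lt$yday + 1
  leap <- (lt$year + 1900) %% 4 == 0 &
    ((lt$year + 1900) %% 100 != 0 | (lt$year + 1900) %% 400 == 0)
  doy[leap & doy >= 60] <- doy[leap & doy >= 60] - 1L
  doy
}

#' Assemble per-cell daily forcing from climatologies
#'
#' Combines SST and chlorophyll climatologies defined on the same grid into
#' a \code{grid_forcing}: per-cell daily series over the requested calendar
#' window, with POC derived at a fixed ratio and photoperiod computed from
#' each cell's latitude. Ice can be supplied as a logical matrix
#' (cells x days).
#'
#' @param sst_clim,chl_clim \code{grid_climatology} objects on identical
#'   cells.
#' @param start,end calendar window (Dates or strings).
#' @param ice logical, or matrix cells x days.
#' @param poc_ratio mg C per mg chlorophyll a.
#' @return object of class \code{grid_forcing}.
#' @export
grid_forcing <- function(sst_clim, chl_clim, start = "2009-11-01",
                         end = "2010-04-15", ice = FALSE, poc_ratio = 50) {
  stopifnot(inherits(sst_clim, "grid_climatology"),
            inherits(chl_clim, "grid_climatology"))
  if (!identical(sst_clim$cells, chl_clim$cells))
    stop("SST and chlorophyll climatologies are on different cells")
  dates <- seq(as.Date(start), as.Date(end), by = "day")
  doy <- day_of_year_365(dates)
  ncell <- nrow(sst_clim$cells)
  sst <- sst_clim$values[, doy, drop = FALSE]
  chl <- pmax(chl_clim$values[, doy, drop = FALSE], 0)
  pp <- outer(sst_clim$cells$lat, doy, compute_photoperiod)
  if (is.matrix(ice)) {
    stopifnot(dim(ice) == c(ncell, length(dates)))
    icem <- ice
  } else {
    icem <- matrix(rep_len(as.logical(ice), 1), ncell, length(dates))
  }
  structure(list(cells = cbind(sst_clim$cells,
                               masked = rep(FALSE, ncell)),
                 dates = dates, sst = sst, chl = chl,
                 poc = poc_ratio * chl, photoperiod = pp, ice = icem,
                 poc_ratio = poc_ratio),
            class = "grid_forcing")
}

#' Build a grid forcing directly from arrays (toy grids, tests)
#'
#' @param lon,lat cell-centre coordinate vectors (one entry per cell).
#' @param dates contiguous daily Date vector.
#' @param sst,chl matrices cells x days.
#' @param ice logical matrix cells x days (default no ice).
#' @param poc_ratio mg C per mg chlorophyll a.
#' @return object of class \code{grid_forcing}.
#' @export
grid_forcing_from_arrays <- function(lon, lat, dates, sst, chl,
                                     ice = NULL, poc_ratio = 50) {
  dates <- as.Date(dates)
  ncell <- length(lon)
  stopifnot(length(lat) == ncell,
            dim(sst) == c(ncell, length(dates)),
            dim(chl) == c(ncell, length(dates)))
  if (is.null(ice)) ice <- matrix(FALSE, ncell, length(dates))
  doy <- day_of_year_365(dates)
  pp <- outer(lat, doy, compute_photoperiod)
  structure(list(cells = data.frame(lon = lon, lat = lat,
                                    masked = rep(FALSE, ncell)),
                 dates = dates, sst = sst, chl = pmax(chl, 0),
                 poc = poc_ratio * pmax(chl, 0), photoperiod = pp,
                 ice = ice, poc_ratio = poc_ratio),
            class = "grid_forcing")
}

#' Extract the forcing series of one grid cell
#'
#' @param grid a \code{grid_forcing}.
#' @param cell cell index (row of \code{grid$cells}).
#' @return an \code{environmental_forcing} data frame.
#' @export
cell_forcing <- function(grid, cell) {
  environmental_forcing(date = grid$dates, sst = grid$sst[cell, ],
                        chl = grid$chl[cell, ],
                        photoperiod = grid$photoperiod[cell, ],
                        ice = grid$ice[cell, ],
                        latitude = grid$cells$lat[cell],
                        longitude = grid$cells$lon[cell],
                        poc_ratio = grid$poc_ratio)
}

#' Mask grid cells north of the Polar Front
#'
#' The boundary is a polyline of (lon, lat) pairs spanning all longitudes
#' (closed around the pole). Cells whose centre lies north of the
#' interpolated boundary latitude at their longitude are masked out.
#'
#' @param grid a \code{grid_forcing}.
#' @param boundary data frame with columns \code{lon}, \code{lat}.
#' @return the grid with its \code{masked} column updated.
#' @export
apply_polar_front_mask <- function(grid, boundary) {
  stopifnot(inherits(grid, "grid_forcing"),
            all(c("lon", "lat") %in% names(boundary)))
  b <- boundary[order(boundary$lon), ]
  gaps <- diff(c(b$lon, b$lon[1] + 360))
  if (max(gaps) > 30)
    stop("polar-front boundary is not longitude-complete")
  # wrap the polyline so interpolation works across the date line
  lon_ext <- c(b$lon - 360, b$lon, b$lon + 360)
  lat_ext <- rep(b$lat, 3)
  bl <- stats::approx(lon_ext, lat_ext, xout = grid$cells$lon)$y
  grid$cells$masked <- grid$cells$lat > bl
  grid
}

#' Mean polar-front boundary from weekly polylines
#'
#' Interpolates each weekly boundary onto a common longitude grid and
#' averages the latitudes per longitude.
#'
#' @param weekly list of data frames with columns \code{lon}, \code{lat}.
#' @param lon_out longitudes of the output polyline.
#' @return data frame with columns \code{lon}, \code{lat}.
#' @export
polar_front_mean_boundary <- function(weekly,
                                      lon_out = seq(-180, 179.5, by = 0.5)) {
  stopifnot(length(weekly) >= 1)
  lats <- vapply(weekly, function(w) {
    w <- w[order(w$lon), ]
    lon_ext <- c(w$lon - 360, w$lon, w$lon + 360)
    stats::approx(lon_ext, rep(w$lat, 3), xout = lon_out)$y
  }, numeric(length(lon_out)))
  data.frame(lon = lon_out, lat = rowMeans(matrix(lats, nrow = length(lon_out))))
}
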