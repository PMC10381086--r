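# Environmental forcing: photoperiod, food-proxy conversion, smoothing and
# the synthetic South-Orkney-style seasonal driver series.

#' Hours of daylight from latitude and day of year
#'
#' Photoperiod is defined as the time between sunrise and sunset, computed
#' from the standard solar-declination sunrise equation with the sun centre
#' at -0.833 degrees elevation (refraction plus solar semidiameter). Inside
#' the polar circles the value saturates at 0 (polar night) or 24 h
#' (polar day); no twilight correction is applied.
#'
#' @param latitude degrees, negative south; must satisfy |latitude| <= 90.
#' @param day_of_year numeric day of year in [1, 365] (fractional values are
#'   accepted, e.g. for hemispheric-mirror checks).
#' @return photoperiod in hours, in [0, 24]. Vectorised over both arguments.
#' @export
compute_photoperiod <- function(latitude, day_of_year) {
  if (any(abs(latitude) > 90)) stop("|latitude| must be <= 90 degrees")
  if (any(day_of_year < 1 | day_of_year > 365.5))
    stop("day_of_year must lie in [1, 365]")
  deg2rad <- pi / 180
  # solar declination (degrees), simple cosine model
  decl <- -23.44 * cos(2 * pi * (day_of_year + 10) / 365)
  h0 <- -0.833 * deg2rad
  phi <- latitude * deg2rad
  delta <- decl * deg2rad
  cosw <- (sin(h0) - sin(phi) * sin(delta)) / (cos(phi) * cos(delta))
  cosw <- pmin(1, pmax(-1, cosw))  # saturate: polar day / polar night
  24 * acos(cosw) / pi
}

#' Convert chlorophyll a to particulate organic carbon
#'
#' Fixed-ratio conversion used by the carbon-based bioenergetic models;
#' the default ratio is 50 mg C per mg chlorophyll a.
#'
#' @param chl chlorophyll a concentration, mg m-3; must be non-negative.
#' @param ratio mg C per mg chlorophyll a.
#' @return POC in mg C m-3.
#' @export
chl_to_poc <- function(chl, ratio = 50) {
  if (any(chl < 0, na.rm = TRUE)) stop("chl must be non-negative")
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0)
    stop("ratio must be a positive scalar")
  ratio * chl
}

#' Centred rolling mean with missing-value tolerance
#'
#' Smooths a daily series with a centred window, ignoring missing values
#' (the mean is taken over available observations inside the window; partial
#' windows at the series edges use the in-range positions). A window whose
#' observations are all missing yields NA.
#'
#' @param series numeric vector (daily values, may contain NA).
#' @param window odd positive integer window width in days.
#' @return numeric vector of the same length as \code{series}.
#' @export
rolling_mean_smooth <- function(series, window = 15) {
  if (length(window) != 1L || window < 1 || window %% 2 != 1)
    stop("window must be an odd positive integer")
  n <- length(series)
  if (n < window) stop("series must be at least as long as the window")
  k <- (window - 1) / 2
  out <- vapply(seq_len(n), function(i) {
    w <- series[max(1L, i - k):min(n, i + k)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
  out
}

#' Configuration for the synthetic seasonal forcing generator
#'
#' Defaults emulate a productive spring-to-fall season south of the South
#' Orkney Islands: sea-surface temperature of -1.5 degC and chlorophyll a of
#' 0.3 mg m-3 on 1 November, a sinusoidal temperature cycle peaking in
#' mid-February, a Gaussian mid-season bloom peaking in late January, and
#' chlorophyll declining back towards the baseline from late February.
#'
#' @param latitude,longitude location, degrees (negative south/west).
#' @param start,end simulation window (1 November to 15 April, 166 days).
#' @param sst_start SST on the start date, degC.
#' @param sst_peak seasonal SST maximum, degC.
#' @param sst_peak_date date of the SST maximum.
#' @param chl_base baseline chlorophyll a, mg m-3.
#' @param bloom_amplitude bloom height above baseline, mg m-3 (>= 0).
#' @param bloom_peak date of the bloom maximum.
#' @param bloom_sd bloom width (Gaussian standard deviation), days (> 0).
#' @param noise_sd_sst,noise_sd_chl optional Gaussian noise SD (>= 0).
#' @param poc_ratio mg C per mg chlorophyll a.
#' @param ice logical scalar or vector: daily sea-ice flag.
#' @return a list of class \code{soi_forcing_config}.
#' @export
soi_forcing_config <- function(latitude = -60.7, longitude = -45.0,
                               start = "2009-11-01", end = "2010-04-15",
                               sst_start = -1.5, sst_peak = 1.2,
                               sst_peak_date = "2010-02-10",
                               chl_base = 0.3, bloom_amplitude = 0.9,
                               bloom_peak = "2010-01-20", bloom_sd = 28,
                               noise_sd_sst = 0, noise_sd_chl = 0,
                               poc_ratio = 50, ice = FALSE) {
  if (bloom_amplitude < 0) stop("bloom_amplitude must be non-negative")
  if (bloom_sd <= 0) stop("bloom_sd must be positive")
  if (noise_sd_sst < 0 || noise_sd_chl < 0)
    stop("noise standard deviations must be non-negative")
  if (chl_base < 0) stop("chl_base must be non-negative")
  cfg <- list(latitude = latitude, longitude = longitude,
              start = as.Date(start), end = as.Date(end),
              sst_start = sst_start, sst_peak = sst_peak,
              sst_peak_date = as.Date(sst_peak_date),
              chl_base = chl_base, bloom_amplitude = bloom_amplitude,
              bloom_peak = as.Date(bloom_peak), bloom_sd = bloom_sd,
              noise_sd_sst = noise_sd_sst, noise_sd_chl = noise_sd_chl,
              poc_ratio = poc_ratio, ice = ice)
  class(cfg) <- "soi_forcing_config"
  cfg
}

#' Generate synthetic South-Orkney-style daily forcing
#'
#' Produces a contiguous daily series of SST, chlorophyll a, derived POC,
#' photoperiod and ice flag over the configured window (166 days at the
#' defaults). The SST sinusoid passes exactly through the configured start
#' anchor and seasonal peak; chlorophyll is a Gaussian bloom on a constant
#' baseline. With a non-zero noise SD the series is reproducible for a
#' fixed \code{seed}.
#'
#' @param config a \code{\link{soi_forcing_config}}.
#' @param seed optional integer seed for the noise terms.
#' @return an \code{environmental_forcing} data frame with columns
#'   \code{date, sst, chl, poc, photoperiod, ice} and latitude/longitude
#'   attributes.
#' @export
synthetic_soi_forcing <- function(config = soi_forcing_config(), seed = NULL) {
  stopifnot(inherits(config, "soi_forcing_config"))
  dates <- seq(config$start, config$end, by = "day")
  n <- length(dates)
  d <- as.numeric(dates - config$sst_peak_date)
  c0 <- cos(2 * pi * as.numeric(config$start - config$sst_peak_date) / 365)
  amp <- (config$sst_peak - config$sst_start) / (1 - c0)
  sst <- (config$sst_peak - amp) + amp * cos(2 * pi * d / 365)
  db <- as.numeric(dates - config$bloom_peak)
  chl <- config$chl_base +
    config$bloom_amplitude * exp(-0.5 * (db / config$bloom_sd)^2)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (config$noise_sd_sst > 0) sst <- sst + stats::rnorm(n, 0, config$noise_sd_sst)
  if (config$noise_sd_chl > 0)
    chl <- pmax(0, chl + stats::rnorm(n, 0, config$noise_sd_chl))
  doy <- as.POSIXlt(dates)$yday + 1
  doy[doy > 365] <- 365
  environmental_forcing(
    date = dates, sst = sst, chl = chl,
    photoperiod = compute_photoperiod(config$latitude, doy),
    ice = rep_len(as.logical(config$ice), n),
    latitude = config$latitude, longitude = config$longitude,
    poc_ratio = config$poc_ratio)
}

#' Construct and validate an environmental forcing series
#'
#' @param date contiguous daily Date vector.
#' @param sst sea-surface temperature, degC.
#' @param chl chlorophyll a, mg m-3 (non-negative).
#' @param photoperiod hours in [0, 24].
#' @param ice logical daily sea-ice flag.
#' @param latitude,longitude location, degrees.
#' @param poc_ratio mg C per mg chlorophyll a used to derive POC.
#' @param poc optional POC column; derived from \code{chl} when missing.
#' @return data frame of class \code{environmental_forcing}.
#' @export
environmental_forcing <- function(date, sst, chl, photoperiod,
                                  ice = FALSE, latitude = NA_real_,
                                  longitude = NA_real_, poc_ratio = 50,
                                  poc = NULL) {
  date <- as.Date(date)
  n <- length(date)
  if (n > 1 && !all(diff(as.numeric(date)) == 1))
    stop("forcing series must be contiguous daily with no gaps")
  if (any(chl < 0, na.rm = TRUE)) stop("chl must be non-negative")
  if (any(photoperiod < 0 | photoperiod > 24, na.rm = TRUE))
    stop("photoperiod must lie in [0, 24]")
  if (is.null(poc)) poc <- chl_to_poc(chl, poc_ratio)
  out <- data.frame(date = date, sst = sst, chl = chl, poc = poc,
                    photoperiod = photoperiod,
                    ice = rep_len(as.logical(ice), n))
  attr(out, "latitude") <- latitude
  attr(out, "longitude") <- longitude
  attr(out, "poc_ratio") <- poc_ratio
  class(out) <- c("environmental_forcing", "data.frame")
  out
}

#' Write / read single-location forcing as CSV
#'
#' Plain-text interchange format: columns
#' \code{date,sst,chl,poc,photoperiod,ice} plus latitude/longitude stored in
#' \code{#}-prefixed header comments.
#'
#' @param forcing an \code{environmental_forcing} object.
#' @param path file path.
#' @return \code{read_forcing_csv} returns an \code{environmental_forcing}.
#' @export
write_forcing_csv <- function(forcing, path) {
  stopifnot(inherits(forcing, "environmental_forcing"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# latitude: %s", attr(forcing, "latitude")), con)
  writeLines(sprintf("# longitude: %s", attr(forcing, "longitude")), con)
  writeLines(sprintf("# poc_ratio: %s", attr(forcing, "poc_ratio")), con)
  utils::write.csv(as.data.frame(forcing), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_forcing_csv
#' @export
read_forcing_csv <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  get_attr <- function(key) {
    ln <- grep(sprintf("^# %s:", key), hdr, value = TRUE)
    if (length(ln)) as.numeric(sub(".*: *", "", ln[1])) else NA_real_
  }
  df <- utils::read.csv(path, comment.char = "#")
  environmental_forcing(date = df$date, sst = df$sst, chl = df$chl,
                        photoperiod = df$photoperiod, ice = df$ice,
                        latitude = get_attr("latitude"),
                        longitude = get_attr("longitude"),
                        poc_ratio = if (is.na(get_attr("poc_ratio"))) 50
                                    else get_attr("poc_ratio"),
                        poc = df$poc)
}
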