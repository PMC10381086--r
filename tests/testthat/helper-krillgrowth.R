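# Shared helpers: independent oracles and small constructors used across
# the test files.

# Independent almanac oracle for day length: NOAA solar-position algorithm
# with the Fourier-series declination (Spencer), horizon at -0.833 deg.
# Deliberately a different declination model from the package's.
noaa_daylength <- function(lat, doy) {
  gamma <- 2 * pi / 365 * (doy - 1 + 0.5)
  decl <- 0.006918 - 0.399912 * cos(gamma) + 0.070257 * sin(gamma) -
    0.006758 * cos(2 * gamma) + 0.000907 * sin(2 * gamma) -
    0.002697 * cos(3 * gamma) + 0.00148 * sin(3 * gamma)
  phi <- lat * pi / 180
  h0 <- -0.833 * pi / 180
  cosw <- (sin(h0) - sin(phi) * sin(decl)) / (cos(phi) * cos(decl))
  24 * acos(pmin(1, pmax(-1, cosw))) / pi
}

# Constant-conditions daily forcing over n days starting 1 November.
const_forcing <- function(sst, chl, n = 166, ice = FALSE,
                          latitude = -60.7, start = "2009-11-01") {
  dates <- seq(as.Date(start), by = "day", length.out = n)
  doy <- as.POSIXlt(dates)$yday + 1
  doy[doy > 365] <- 365
  environmental_forcing(date = dates, sst = rep(sst, n), chl = rep(chl, n),
                        photoperiod = compute_photoperiod(latitude, doy),
                        ice = ice, latitude = latitude)
}

# Coarse axes keep the per-model surface loops fast in tests.
coarse_sst <- seq(-2, 4, by = 0.25)
coarse_chl <- seq(0, 5, by = 0.25)
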