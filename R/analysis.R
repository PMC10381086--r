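# Intercomparison analytics: response surfaces, required-chlorophyll
# inversion, trajectory-ensemble spread and cross-model divergence maps.

#' Temperature-by-chlorophyll response surface
#'
#' Evaluates a model's daily growth rate for a fixed body length under
#' every combination of constant temperature and chlorophyll. For the
#' moult-based composites the daily rate is the moult increment divided by
#' the intermoult period, with the IMP-mean conditions equal to the point
#' values in this constant-forcing limit. Photoperiod is an explicit
#' argument (only the photoperiod-DEB model is sensitive to it).
#'
#' @param model \code{krill_model} or id.
#' @param length body length, mm (default 26).
#' @param date reference date (affects only models with a winter switch;
#'   the default mid-January is outside every configured window).
#' @param photoperiod day length, hours (default 20).
#' @param sst_axis,chl_axis strictly increasing axes.
#' @param config optional \code{simulation_config} (e.g. unlimited food).
#' @return object of class \code{response_surface}: axes plus a
#'   \code{|sst_axis| x |chl_axis|} rate matrix, mm d-1.
#' @export
response_surface <- function(model, length = 26,
                             date = as.Date("2010-01-15"), photoperiod = 20,
                             sst_axis = seq(-2, 4, by = 0.05),
                             chl_axis = seq(0, 5, by = 0.05),
                             config = list()) {
  if (is.character(model)) model <- krill_model(model)
  if (any(diff(sst_axis) <= 0) || any(diff(chl_axis) <= 0))
    stop("axes must be strictly increasing")
  rate <- matrix(NA_real_, length(sst_axis), length(chl_axis))
  for (i in seq_along(sst_axis))
    for (j in seq_along(chl_axis))
      rate[i, j] <- model$rate(length, sst_axis[i], chl_axis[j],
                               photoperiod = photoperiod, date = date,
                               config = config)
  if (!all(is.finite(rate))) stop("non-finite surface entries")
  structure(list(model = model$id, length = length, date = date,
                 photoperiod = photoperiod, sst = sst_axis, chl = chl_axis,
                 rate = rate),
            class = "response_surface")
}

#' @export
print.response_surface <- function(x, ...) {
  i <- which(x$rate == max(x$rate), arr.ind = TRUE)[1, ]
  cat(sprintf("<response_surface> %s at %g mm\n", x$model, x$length))
  cat(sprintf("  rate range [%.3f, %.3f] mm/d; max at sst %.2f degC, chl %.2f mg m-3\n",
              min(x$rate), max(x$rate), x$sst[i[1]], x$chl[i[2]]))
  invisible(x)
}

#' @export
plot.response_surface <- function(x, ...) {
  graphics::filled.contour(x$sst, x$chl, x$rate,
                           xlab = "SST (degC)",
                           ylab = "chlorophyll a (mg m-3)",
                           main = sprintf("%s, %g mm", x$model, x$length),
                           ...)
  invisible(x)
}

#' Minimum chlorophyll needed to reach a target growth rate
#'
#' Inverts a model's (monotone non-decreasing) chlorophyll response at
#' fixed temperature, length and photoperiod by bisection on [0, upper] to
#' a 1e-3 mg m-3 tolerance. Returns NA (flagged "unreachable") when even
#' saturating food cannot reach the target, e.g. beyond the 0.25 mm/d cap
#' of the clearance-feeding models.
#'
#' @param model \code{krill_model} or id.
#' @param target_rate mm d-1.
#' @param sst water temperature, degC.
#' @param length body length, mm.
#' @param photoperiod hours.
#' @param date reference date.
#' @param upper upper end of the search interval, mg m-3.
#' @param tol chlorophyll tolerance, mg m-3.
#' @return chlorophyll a in mg m-3, or NA with attribute
#'   \code{status = "unreachable"}.
#' @export
required_chl <- function(model, target_rate, sst, length = 26,
                         photoperiod = 20, date = as.Date("2010-01-15"),
                         upper = 20, tol = 1e-3) {
  if (is.character(model)) model <- krill_model(model)
  f <- function(chl) model$rate(length, sst, chl, photoperiod = photoperiod,
                                date = date)
  grid <- f(seq(0, upper, length.out = 81))
  if (any(diff(grid) < -1e-9))
    stop("model response is not monotone non-decreasing in chlorophyll")
  if (f(0) >= target_rate) return(0)
  if (f(upper) < target_rate)
    return(structure(NA_real_, status = "unreachable"))
  lo <- 0; hi <- upper
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) >= target_rate) hi <- mid else lo <- mid
  }
  hi
}

#' Per-day ensemble mean and spread of trajectories
#'
#' @param ensemble a \code{krill_ensemble} (>= 2 aligned trajectories).
#' @return data frame: \code{date}, \code{mean_mm}, \code{sd_mm} (population
#'   standard deviation over models, i.e. divide by N), \code{n_models}.
#' @export
ensemble_spread <- function(ensemble) {
  stopifnot(length(ensemble) >= 2)
  dates <- ensemble[[1]]$date
  for (tr in ensemble)
    if (!identical(tr$date, dates)) stop("trajectory dates are misaligned")
  lens <- sapply(ensemble, function(tr) tr$length_mm)
  mu <- rowMeans(lens)
  sdp <- sqrt(rowMeans((lens - mu)^2))
  data.frame(date = dates, mean_mm = mu, sd_mm = sdp,
             n_models = length(ensemble))
}

#' Cross-model divergence map
#'
#' Per-cell mean, population standard deviation and coefficient of
#' variation (CV = SD / |mean|) of the final body lengths across models.
#' Cells whose |mean| falls below \code{mean_floor} get an undefined CV
#' (NA) and are flagged rather than dropped.
#'
#' @param result a \code{krill_grid_result}, or a matrix cells x models of
#'   final values.
#' @param mean_floor smallest |mean| for which the CV is defined, mm.
#' @param cells optional data frame of cell coordinates when a bare matrix
#'   is supplied.
#' @return data frame of class \code{divergence_map}: lon, lat, mean, sd,
#'   cv, flagged.
#' @export
divergence_map <- function(result, mean_floor = 0.1, cells = NULL) {
  if (inherits(result, "krill_grid_result")) {
    vals <- result$final
    cells <- result$cells
  } else {
    vals <- as.matrix(result)
    if (is.null(cells))
      cells <- data.frame(lon = NA_real_, lat = NA_real_)[rep(1, nrow(vals)), ]
  }
  if (ncol(vals) < 2) stop("divergence map needs at least two models")
  mu <- rowMeans(vals)
  sdp <- sqrt(rowMeans((vals - mu)^2))
  cv <- ifelse(!is.na(mu) & abs(mu) >= mean_floor, sdp / abs(mu), NA_real_)
  out <- data.frame(lon = cells$lon, lat = cells$lat, mean = mu, sd = sdp,
                    cv = cv, flagged = !is.na(mu) & abs(mu) < mean_floor)
  class(out) <- c("divergence_map", "data.frame")
  out
}

#' Export a response surface as a long-format CSV
#'
#' @param surface a \code{response_surface}.
#' @param path output file.
#' @export
write_surface_csv <- function(surface, path) {
  stopifnot(inherits(surface, "response_surface"))
  long <- expand.grid(sst = surface$sst, chl = surface$chl)
  long$rate <- as.vector(surface$rate)
  long$model <- surface$model
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
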