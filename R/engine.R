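# Simulation engine: the common protocol (166-day window, daily stepping,
# ice-rule precedence, Euler/RK4 integrators) for single locations and
# grids.

#' Simulation configuration
#'
#' @param start,end simulation window, both endpoints inclusive (defaults:
#'   1 November to 15 April, 166 daily states).
#' @param initial_length starting body length, mm; at least 26 mm, the
#'   smallest size all eight models are calibrated for.
#' @param integrator "euler" or "rk4" (rate/ODE models only; moult-based
#'   models are event processes and always step daily).
#' @param charge_ice_metabolism if TRUE, mechanistic models pay metabolic
#'   costs (with zero food) on ice-covered days instead of being frozen.
#' @param unlimited_food if TRUE the DEB models run with functional
#'   response fixed at 1.
#' @param increment_floor optional lower bound on moult increments
#'   (e.g. 0 disables shrinkage at moult); NULL applies none.
#' @param seed optional integer recorded in the run manifest.
#' @return list of class \code{simulation_config}.
#' @export
simulation_config <- function(start = "2009-11-01", end = "2010-04-15",
                              initial_length = 26,
                              integrator = c("euler", "rk4"),
                              charge_ice_metabolism = FALSE,
                              unlimited_food = FALSE,
                              increment_floor = NULL, seed = NULL) {
  start <- as.Date(start); end <- as.Date(end)
  if (end <= start) stop("end must fall after start")
  if (initial_length < 26)
    stop("initial length below the smallest common calibrated size (26 mm)")
  structure(list(start = start, end = end,
                 n_days = as.integer(end - start) + 1L,
                 initial_length = initial_length,
                 integrator = match.arg(integrator),
                 charge_ice_metabolism = charge_ice_metabolism,
                 unlimited_food = unlimited_food,
                 increment_floor = increment_floor, seed = seed),
            class = "simulation_config")
}

env_row <- function(forcing, i) {
  list(sst = forcing$sst[i], chl = forcing$chl[i], poc = forcing$poc[i],
       photoperiod = forcing$photoperiod[i], ice = forcing$ice[i])
}

env_mid <- function(a, b) {
  list(sst = (a$sst + b$sst) / 2, chl = (a$chl + b$chl) / 2,
       poc = (a$poc + b$poc) / 2,
       photoperiod = (a$photoperiod + b$photoperiod) / 2)
}

zero_food <- function(env) {
  env$chl <- 0; env$poc <- 0
  env
}

step_euler <- function(model, length, env, date, config) {
  length + model$deriv(length, env, date, config)
}

# RK4 over one day with the forcing interpolated linearly between the
# daily values of this day and the next.
step_rk4 <- function(model, length, env, env_next, date, config) {
  em <- env_mid(env, env_next)
  k1 <- model$deriv(length, env, date, config)
  k2 <- model$deriv(length + k1 / 2, em, date, config)
  k3 <- model$deriv(length + k2 / 2, em, date, config)
  k4 <- model$deriv(length + k3, env_next, date, config)
  length + (k1 + 2 * k2 + 2 * k3 + k4) / 6
}

#' Simulate one krill's growth trajectory
#'
#' Advances one individual through the forcing series under the common
#' protocol: one state per calendar day (the recorded length is the length
#' at the start of that day; the first record is the initial length). On
#' ice-covered days growth is zero, metabolism is not charged (unless
#' configured otherwise) and moult clocks are extended by one day.
#' The run is deterministic given config, registry and forcing.
#'
#' @param model a \code{krill_model} or model id.
#' @param forcing an \code{environmental_forcing} covering the window with
#'   no gaps.
#' @param config a \code{\link{simulation_config}}.
#' @return data frame of class \code{krill_trajectory}: \code{date},
#'   \code{length_mm}, \code{stage}, \code{moulted}, \code{imp_days}; the
#'   model id, config and final length change are attached as attributes.
#' @export
simulate_trajectory <- function(model, forcing,
                                config = simulation_config()) {
  if (is.character(model)) model <- krill_model(model)
  stopifnot(inherits(model, "krill_model"),
            inherits(forcing, "environmental_forcing"),
            inherits(config, "simulation_config"))
  dates <- seq(config$start, config$end, by = "day")
  idx <- match(dates, forcing$date)
  if (anyNA(idx))
    stop("forcing does not cover the simulation window without gaps")
  missing_req <- model$requires[vapply(model$requires, function(v)
    !v %in% names(forcing) || anyNA(forcing[[v]][idx]), logical(1))]
  if (length(missing_req))
    stop("model '", model$id, "' requires forcing input(s) not supplied: ",
         paste(missing_req, collapse = ", "))
  n <- length(dates)
  state <- model$init(config$initial_length, env_row(forcing, idx[1]), config)
  lengths <- numeric(n); stages <- character(n)
  moulted <- logical(n); imps <- rep(NA_real_, n)
  lengths[1] <- state$length; stages[1] <- state$stage
  if (model$moult_based) imps[1] <- state$clock$imp_days
  for (d in seq_len(n - 1)) {
    env <- env_row(forcing, idx[d])
    if (isTRUE(env$ice)) {
      if (model$moult_based) {
        state <- moult_ice_day(state)
      } else if (config$charge_ice_metabolism) {
        state$length <- step_euler(model, state$length, zero_food(env),
                                   dates[d], config)
      } # else: physics frozen, length unchanged
    } else if (model$moult_based) {
      state <- moult_step(state, env, model$imp_fn, model$dgr_fn,
                          model_id = model$id,
                          increment_floor = config$increment_floor)
    } else {
      state$length <- if (config$integrator == "rk4")
        step_rk4(model, state$length, env, env_row(forcing, idx[d + 1]),
                 dates[d], config)
      else step_euler(model, state$length, env, dates[d], config)
      state$stage <- stage_select(state$length, model$id)
    }
    if (!is.finite(state$length))
      stop("non-finite state in model '", model$id, "' on ", dates[d])
    lengths[d + 1] <- state$length
    stages[d + 1] <- state$stage
    moulted[d + 1] <- isTRUE(state$moulted)
    imps[d + 1] <- if (model$moult_based) state$clock$imp_days else NA_real_
  }
  out <- data.frame(date = dates, length_mm = lengths, stage = stages,
                    moulted = moulted, imp_days = imps)
  attr(out, "model_id") <- model$id
  attr(out, "config") <- config
  attr(out, "final_change") <- lengths[n] - lengths[1]
  class(out) <- c("krill_trajectory", "data.frame")
  out
}

#' @export
print.krill_trajectory <- function(x, ...) {
  cat(sprintf("<krill_trajectory> %s: %d daily states, %s to %s\n",
              attr(x, "model_id"), nrow(x), format(x$date[1]),
              format(x$date[nrow(x)])))
  cat(sprintf("  length %.1f -> %.1f mm (change %+.2f mm), %d moults\n",
              x$length_mm[1], x$length_mm[nrow(x)],
              attr(x, "final_change"), sum(x$moulted)))
  invisible(x)
}

#' @export
plot.krill_trajectory <- function(x, ...) {
  plot(x$date, x$length_mm, type = "s", xlab = "date",
       ylab = "body length (mm)", main = attr(x, "model_id"), ...)
  invisible(x)
}

#' Simulate an ensemble of models on shared forcing
#'
#' @param models "all", a character vector of ids, or a list of
#'   \code{krill_model}s.
#' @inheritParams simulate_trajectory
#' @return named list of trajectories, class \code{krill_ensemble}.
#' @export
simulate_ensemble <- function(models = "all", forcing,
                              config = simulation_config()) {
  if (is.character(models)) models <- krill_models(models)
  out <- lapply(models, simulate_trajectory, forcing = forcing,
                config = config)
  class(out) <- "krill_ensemble"
  out
}

#' @export
print.krill_ensemble <- function(x, ...) {
  cat(sprintf("<krill_ensemble> %d models\n", length(x)))
  for (tr in x)
    cat(sprintf("  %-14s final %6.2f mm (%+.2f)\n", attr(tr, "model_id"),
                tr$length_mm[nrow(tr)], attr(tr, "final_change")))
  invisible(x)
}

#' @export
plot.krill_ensemble <- function(x, ...) {
  dates <- x[[1]]$date
  lens <- sapply(x, function(tr) tr$length_mm)
  graphics::matplot(dates, lens, type = "l", lty = 1, xlab = "date",
                    ylab = "body length (mm)", ...)
  graphics::legend("topleft", legend = names(x), col = seq_along(x),
                   lty = 1, cex = 0.7, bty = "n")
  invisible(x)
}

#' Simulate all models over a forcing grid
#'
#' Runs each model independently in every unmasked grid cell and collects
#' the final lengths and final length changes. Cells are independent:
#' results do not depend on execution order or chunking.
#'
#' @param models as in \code{\link{simulate_ensemble}}.
#' @param grid a \code{grid_forcing}.
#' @param config a \code{\link{simulation_config}}.
#' @param cells optional integer vector restricting/ordering the simulated
#'   cells (unmasked cells by default); results are returned in grid order
#'   regardless.
#' @return list of class \code{krill_grid_result}: \code{cells} (lon, lat),
#'   \code{final} and \code{change} matrices (cells x models).
#' @export
simulate_grid <- function(models = "all", grid,
                          config = simulation_config(), cells = NULL) {
  stopifnot(inherits(grid, "grid_forcing"))
  if (is.character(models)) models <- krill_models(models)
  active <- which(!grid$cells$masked)
  if (length(active) == 0) stop("grid mask leaves no active cells")
  if (is.null(cells)) cells <- active
  if (!all(cells %in% active)) stop("requested cells include masked cells")
  ids <- vapply(models, `[[`, "", "id")
  final <- matrix(NA_real_, nrow(grid$cells), length(models),
                  dimnames = list(NULL, ids))
  for (cell in cells) {
    fc <- cell_forcing(grid, cell)
    for (j in seq_along(models)) {
      tr <- simulate_trajectory(models[[j]], fc, config)
      final[cell, j] <- tr$length_mm[nrow(tr)]
    }
  }
  structure(list(cells = grid$cells[, c("lon", "lat")], models = ids,
                 final = final, change = final - config$initial_length,
                 config = config),
            class = "krill_grid_result")
}
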