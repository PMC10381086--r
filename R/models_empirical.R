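# Empirical growth machinery: instantaneous daily growth rate, the two
# intermoult-period (IMP) functions, moult increments and the moult clock.

#' Instantaneous daily growth rate (Atkinson-type)
#'
#' Additive regression of daily length growth on body length (quadratic),
#' temperature (quadratic) and a saturating (Michaelis-Menten) chlorophyll
#' term. May be negative; strictly non-decreasing in chlorophyll.
#'
#' @param length body length, mm.
#' @param sst water temperature, degC.
#' @param chl chlorophyll a, mg m-3 (non-negative).
#' @param params a \code{parameter_set} from the \code{dgr} block of the
#'   \code{atkinson2006} registry entry.
#' @return growth rate, mm d-1 (vectorised).
#' @export
atkinson_dgr <- function(length, sst, chl, params) {
  stopifnot(inherits(params, "parameter_set"))
  if (any(chl < 0)) stop("chl must be non-negative")
  co <- params$coefficients
  co[["a0"]] + co[["aL"]] * length + co[["aL2"]] * length^2 +
    co[["aF"]] * chl / (co[["kF"]] + chl) +
    co[["aT"]] * sst + co[["aT2"]] * sst^2
}

#' Moult increment (Atkinson-type), mm per moult
#'
#' The per-moult growth increment as a percentage of body length, from the
#' same regression family as \code{\link{atkinson_dgr}} (saturating food
#' term, quadratic temperature term), converted to mm.
#'
#' @inheritParams atkinson_dgr
#' @param params a \code{parameter_set} from the \code{increment} block of
#'   the \code{atkinson2006} registry entry.
#' @return length increment at moult, mm (may be negative).
#' @export
atkinson_increment <- function(length, sst, chl, params) {
  stopifnot(inherits(params, "parameter_set"))
  if (any(chl < 0)) stop("chl must be non-negative")
  co <- params$coefficients
  gi_percent <- co[["g0"]] + co[["gF"]] * chl / (co[["kF"]] + chl) +
    co[["gT"]] * sst + co[["gT2"]] * sst^2
  gi_percent * length / 100
}

#' Temperature-only intermoult period (Kawaguchi-type)
#'
#' Exponential decay of the intermoult period with water temperature;
#' roughly 30 days at 0 degC.
#'
#' @param sst water temperature, degC.
#' @param params a \code{parameter_set} from the \code{imp} block of the
#'   \code{kawaguchi2006} registry entry (loaded when omitted).
#' @return intermoult period, days (positive, decreasing in sst).
#' @export
kawaguchi_imp <- function(sst, params = NULL) {
  if (is.null(params))
    params <- load_parameter_set("kawaguchi2006", "imp", "all krill")
  co <- params$coefficients
  co[["i0"]] * exp(-co[["decay"]] * sst)
}

#' Temperature/length/stage intermoult period (Tarling-type)
#'
#' The intermoult period is the reciprocal of a moulting rate (hyperbolic
#' shape). The juvenile rate is quadratic in temperature with its minimum
#' moulting rate (longest IMP) near 3 degC and no length effect; the
#' adult-female rate peaks at 0.5 degC (IMPs lengthen again above that)
#' and decreases with body length.
#'
#' @param sst water temperature, degC.
#' @param length body length, mm (> 0).
#' @param params a \code{parameter_set} from the \code{imp} block of the
#'   \code{tarling2006} registry entry; its stage must be "juvenile" or
#'   "adult female".
#' @return intermoult period, days (positive).
#' @export
tarling_imp <- function(sst, length, params) {
  stopifnot(inherits(params, "parameter_set"))
  if (any(length <= 0)) stop("length must be positive")
  co <- params$coefficients
  rate <- switch(params$stage,
    "juvenile" = co[["r0"]] + co[["rcurv"]] * (sst - co[["rcentre"]])^2,
    "adult female" = co[["r0"]] + co[["rL"]] * length +
      co[["rT"]] * sst + co[["rT2"]] * sst^2,
    stop("tarling_imp has no '", params$stage, "' parameterization"))
  if (any(rate <= 0))
    stop("moulting rate non-positive outside the model's validity range")
  1 / rate
}

#' Life-stage parameterization from body length
#'
#' Below 35 mm every stage-aware model runs its juvenile parameterization;
#' from 35 mm the Atkinson-based models (including the Kawaguchi-IMP
#' composite) switch to "all krill" and the Tarling composite to
#' "adult female".
#'
#' @param length body length, mm (> 0).
#' @param model_id one of the registry model ids.
#' @return stage label.
#' @export
stage_select <- function(length, model_id) {
  if (any(length <= 0)) stop("length must be positive")
  if (length < 35) return("juvenile")
  switch(model_id,
         tarling2006 = "adult female",
         "all krill")
}

#' Start a moult clock
#'
#' @param imp_days current intermoult period, days.
#' @return a \code{moult_clock} list: IMP duration, days elapsed, ice-day
#'   extensions, and running sums of the forcing experienced on non-ice
#'   days within the IMP.
#' @export
moult_clock <- function(imp_days) {
  stopifnot(imp_days > 0)
  structure(list(imp_days = imp_days, elapsed = 0L, ext = 0L,
                 sst_sum = 0, chl_sum = 0, n_env = 0L),
            class = "moult_clock")
}

# days until moult: clock matures when elapsed >= ceiling(imp) + extensions
clock_mature <- function(clock) {
  clock$elapsed >= ceiling(clock$imp_days) + clock$ext
}

#' Advance a moult-based krill state by one ice-covered day
#'
#' Ice days contribute no growth and no forcing to the within-IMP means;
#' the IMP is extended by one day per ice-covered day.
#'
#' @param state moult-model state (list with \code{length}, \code{stage},
#'   \code{clock}).
#' @return updated state.
#' @export
moult_ice_day <- function(state) {
  state$clock$elapsed <- state$clock$elapsed + 1L
  state$clock$ext <- state$clock$ext + 1L
  state$moulted <- FALSE
  state
}

#' Advance a moult-based krill state by one (open-water) day
#'
#' Between moults the body length is exactly constant: the clock advances
#' and the day's forcing enters the running within-IMP means. On the day
#' the clock matures the krill moults: the length increment is the daily
#' rate returned by \code{dgr_fn} at the IMP-mean forcing multiplied by
#' the IMP duration (ice extensions excluded), the stage is re-evaluated,
#' and a fresh IMP is drawn from \code{imp_fn} at the current conditions.
#'
#' @param state moult-model state (list with \code{length}, \code{stage},
#'   \code{clock}).
#' @param env one row of an \code{environmental_forcing} (list with
#'   \code{sst}, \code{chl}).
#' @param imp_fn function(sst, length, stage) -> IMP days.
#' @param dgr_fn function(length, sst, chl, imp_days, stage) -> mm d-1;
#'   for the composite models this is increment/IMP.
#' @param model_id registry id used for stage re-selection.
#' @param increment_floor optional lower bound applied to the moult
#'   increment (e.g. 0 to disable shrinkage); \code{NULL} leaves negative
#'   increments untouched.
#' @return updated state; \code{state$moulted} flags moult days.
#' @export
moult_step <- function(state, env, imp_fn, dgr_fn, model_id = "",
                       increment_floor = NULL) {
  clock <- state$clock
  clock$elapsed <- clock$elapsed + 1L
  clock$sst_sum <- clock$sst_sum + env$sst
  clock$chl_sum <- clock$chl_sum + env$chl
  clock$n_env <- clock$n_env + 1L
  state$moulted <- FALSE
  if (clock_mature(clock)) {
    mean_sst <- clock$sst_sum / clock$n_env
    mean_chl <- clock$chl_sum / clock$n_env
    dgr <- dgr_fn(state$length, mean_sst, mean_chl, clock$imp_days,
                  state$stage)
    inc <- dgr * clock$imp_days
    if (!is.null(increment_floor)) inc <- max(inc, increment_floor)
    state$length <- state$length + inc
    if (state$length <= 0)
      stop("krill length became non-positive at moult")
    if (nzchar(model_id))
      state$stage <- stage_select(state$length, model_id)
    new_imp <- imp_fn(env$sst, state$length, state$stage)
    state$clock <- moult_clock(new_imp)
    state$moulted <- TRUE
    state$last_imp <- clock$imp_days
  } else {
    state$clock <- clock
  }
  state
}
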