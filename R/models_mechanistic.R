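# Mechanistic energy-budget models: Holling type II food scaling, winter
# metabolic switch, photoperiod scaling, and the daily length-change
# derivatives of the five bioenergetic/DEB models.

#' Holling type II functional response
#'
#' Saturating scaling of food intake: f = chl / (chl + half_saturation),
#' in [0, 1).
#'
#' @param chl food (chlorophyll a) concentration, mg m-3 (non-negative).
#' @param half_saturation half-saturation constant, mg m-3 (> 0).
#' @return dimensionless response in [0, 1).
#' @export
holling_type_II <- function(chl, half_saturation) {
  if (any(half_saturation <= 0)) stop("half_saturation must be positive")
  if (any(chl < 0)) stop("chl must be non-negative")
  chl / (chl + half_saturation)
}

#' Winter metabolic switch
#'
#' Multiplicative reduction of metabolic rates inside a predefined
#' calendar window (late fall to early spring in the source models);
#' factor 1 outside the window.
#'
#' @param date a Date (or "MM-DD" string).
#' @param modifiers list with \code{factor} in (0, 1] and \code{window},
#'   a length-2 character vector of "MM-DD" bounds (inclusive; may wrap
#'   the year end).
#' @return the metabolic factor for that date.
#' @export
winter_switch <- function(date, modifiers) {
  factor <- modifiers$factor
  if (is.null(factor) || factor <= 0 || factor > 1)
    stop("winter switch factor must lie in (0, 1]")
  w <- modifiers$window
  if (is.null(w) || length(w) != 2)
    stop("winter window must give start and end as MM-DD")
  md <- function(x) {
    if (inherits(x, "Date")) {
      lt <- as.POSIXlt(x)
      (lt$mon + 1) * 100 + lt$mday
    } else {
      p <- as.integer(strsplit(as.character(x), "-")[[1]])
      p[1] * 100 + p[2]
    }
  }
  d <- md(date); s <- md(w[1]); e <- md(w[2])
  inside <- if (s <= e) d >= s & d <= e else d >= s | d <= e
  if (inside) factor else 1
}

#' Day-length scaling of metabolic activity
#'
#' Linear, bounded and monotone scaling of ingestion and respiration with
#' photoperiod, applied by the photoperiod-DEB model: activity drops to
#' \code{min_scale} under polar night and reaches 1 under polar day.
#'
#' @param photoperiod hours in [0, 24].
#' @param min_scale activity fraction at zero day length, in (0, 1].
#' @return dimensionless scale in [min_scale, 1].
#' @export
photoperiod_scaling <- function(photoperiod, min_scale = 0.5) {
  if (any(photoperiod < 0 | photoperiod > 24))
    stop("photoperiod must lie in [0, 24]")
  min_scale + (1 - min_scale) * photoperiod / 24
}

# Arrhenius temperature correction relative to the reference temperature.
arrhenius_factor <- function(sst, arrhenius_temp, ref_temp_c = 0) {
  exp(arrhenius_temp / (273.15 + ref_temp_c) - arrhenius_temp / (273.15 + sst))
}

#' Daily length change of the clearance-feeding bioenergetic models
#'
#' Hofmann/Lascara-type energy budget: assimilated carbon from
#' clearance-rate feeding on POC minus Q10 temperature-dependent metabolic
#' costs, mapped through the length-mass coupling; the daily length change
#' is artificially capped at +0.25 mm (shrinkage is not capped). The Fach
#' variant differs only by its registry entries (notably a much weaker
#' temperature dependence of metabolism).
#'
#' @param length body length, mm.
#' @param env list with \code{poc} (mg C m-3) and \code{sst} (degC).
#' @param params \code{parameter_set} from \code{hofmann2000} or
#'   \code{fach2002}.
#' @param winter_factor metabolic switch factor (from
#'   \code{\link{winter_switch}}).
#' @return daily length change, mm d-1 (<= cap).
#' @export
hofmann_fach_rate <- function(length, env, params, winter_factor = 1) {
  co <- params$coefficients
  if (!is.finite(length) || length <= 0) stop("non-finite or non-positive state")
  gain <- co[["ingest_slope"]] * env$poc
  loss <- co[["metab_rate"]] * length * co[["q10"]]^(env$sst / 10) *
    winter_factor
  min(gain - loss, co[["cap"]])
}

#' Daily length change of the DEB growth models
#'
#' DEBkiss somatic budget on the volumetric length Lv = shape x L:
#' assimilation scales with Lv^2 (times the Holling type II response f),
#' somatic maintenance with Lv^3; a fixed fraction kappa of assimilation
#' is allocated to the soma and growth follows from the surplus, so length
#' shrinks when maintenance exceeds the allocated assimilation and growth
#' ceases at the length where the two balance (~60 mm at f = 1). The
#' photoperiod variant multiplies both ingestion and maintenance by the
#' day-length scaling.
#'
#' @param length physical body length, mm.
#' @param env list with \code{sst}, \code{chl} and (photoperiod variant)
#'   \code{photoperiod}.
#' @param params \code{parameter_set} from \code{jager2015} or
#'   \code{bahlburg2021}.
#' @param variant "simplified" or "photoperiod".
#' @param unlimited_food if TRUE the functional response is fixed at 1
#'   (the original simplified-DEB assumption).
#' @return daily length change, mm d-1.
#' @export
deb_rate <- function(length, env, params,
                     variant = c("simplified", "photoperiod"),
                     unlimited_food = FALSE) {
  variant <- match.arg(variant)
  co <- params$coefficients
  kappa <- co[["kappa"]]
  if (kappa <= 0 || kappa >= 1) stop("allocation fraction must lie in (0,1)")
  lv <- co[["shape"]] * length
  f <- if (unlimited_food) 1 else holling_type_II(env$chl, co[["half_saturation"]])
  s <- if (variant == "photoperiod") {
    if (is.null(env$photoperiod))
      stop("photoperiod-DEB model requires photoperiod forcing")
    photoperiod_scaling(env$photoperiod, co[["photoperiod_min_scale"]])
  } else 1
  ct <- arrhenius_factor(env$sst, co[["arrhenius_temp"]], co[["ref_temp_c"]])
  ja <- s * f * co[["assim_max"]] * lv^2   # assimilation flux
  js <- s * co[["maint_rate"]] * lv^3      # somatic maintenance flux
  dlv <- ct * (kappa * ja - js) / (3 * lv^2)
  dlv / co[["shape"]]
}

#' Maintenance (respiration) flux of the DEB models
#'
#' Exposed for intercomparison: the somatic maintenance flux, including
#' the temperature correction and (photoperiod variant) the day-length
#' scaling.
#'
#' @inheritParams deb_rate
#' @return maintenance flux, mg d-1.
#' @export
deb_respiration <- function(length, env, params,
                            variant = c("simplified", "photoperiod")) {
  variant <- match.arg(variant)
  co <- params$coefficients
  lv <- co[["shape"]] * length
  s <- if (variant == "photoperiod")
    photoperiod_scaling(env$photoperiod, co[["photoperiod_min_scale"]])
  else 1
  ct <- arrhenius_factor(env$sst, co[["arrhenius_temp"]], co[["ref_temp_c"]])
  s * ct * co[["maint_rate"]] * lv^3
}

#' Daily length change of the energy-partitioning model (Ryabov-type)
#'
#' Energy intake (Holling type II with a low half-saturation, reflecting
#' the in-situ calibration) is allocated to metabolism first; the residual
#' drives somatic growth. The winter metabolic switch multiplies the
#' metabolic term.
#'
#' @param length body length, mm.
#' @param env list with \code{sst} and \code{chl}.
#' @param params \code{parameter_set} from \code{ryabov2017}.
#' @param winter_factor metabolic switch factor.
#' @return daily length change, mm d-1.
#' @export
ryabov_rate <- function(length, env, params, winter_factor = 1) {
  co <- params$coefficients
  if (!is.finite(length) || length <= 0) stop("non-finite or non-positive state")
  f <- holling_type_II(env$chl, co[["half_saturation"]])
  ct <- arrhenius_factor(env$sst, co[["arrhenius_temp"]], co[["ref_temp_c"]])
  ct * (co[["intake_coef"]] * f - co[["metab_coef"]] * winter_factor * length)
}
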