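# The common GrowthModel contract: every model exposes the same surface
# (initialize a state, advance one day, report an instantaneous daily rate
# under constant conditions, declare required forcing and calibration
# metadata) regardless of whether it is a pure-rate regression, a
# moult-event process or a mechanistic energy budget.

#' Ids of the eight implemented growth models
#'
#' Three empirical models (instantaneous growth rate; two moult-based
#' composites) and five mechanistic models (two clearance-feeding energy
#' budgets, two DEB variants, one energy-partitioning model).
#'
#' @return character vector of model ids.
#' @export
krill_model_ids <- function() {
  c("atkinson2006", "tarling2006", "wiedenmann2008",
    "hofmann2000", "fach2002", "jager2015", "bahlburg2021", "ryabov2017")
}

new_krill_model <- function(id, label, type, requires, metadata,
                            moult_based, init, rate, deriv = NULL,
                            imp_fn = NULL, dgr_fn = NULL) {
  structure(list(id = id, label = label, type = type, requires = requires,
                 metadata = metadata, moult_based = moult_based,
                 init = init, rate = rate, deriv = deriv,
                 imp_fn = imp_fn, dgr_fn = dgr_fn),
            class = "krill_model")
}

#' @export
print.krill_model <- function(x, ...) {
  cat(sprintf("<krill_model> %s: %s\n", x$id, x$label))
  cat(sprintf("  type: %s (%s)\n", x$type,
              if (x$moult_based) "moult-event process" else "daily rate"))
  cat("  requires:", paste(x$requires, collapse = ", "), "\n")
  cat("  calibration region:", x$metadata$calibration$region, "\n")
  invisible(x)
}

#' Construct a growth model by id
#'
#' @param id one of \code{\link{krill_model_ids}}.
#' @param registry_dir optional registry directory override.
#' @return object of class \code{krill_model}.
#' @export
krill_model <- function(id, registry_dir = NULL) {
  builder <- switch(id,
    atkinson2006 = build_atkinson,
    tarling2006 = build_tarling,
    wiedenmann2008 = build_wiedenmann,
    hofmann2000 = function(d) build_hofmann_fach("hofmann2000", d),
    fach2002 = function(d) build_hofmann_fach("fach2002", d),
    jager2015 = function(d) build_deb("jager2015", "simplified", d),
    bahlburg2021 = function(d) build_deb("bahlburg2021", "photoperiod", d),
    ryabov2017 = build_ryabov,
    stop("unknown model id '", id, "'"))
  builder(registry_dir)
}

#' Construct several (or all) growth models
#'
#' @param ids model ids; "all" selects the full suite of eight.
#' @inheritParams krill_model
#' @return named list of \code{krill_model} objects.
#' @export
krill_models <- function(ids = "all", registry_dir = NULL) {
  if (identical(ids, "all")) ids <- krill_model_ids()
  stats::setNames(lapply(ids, krill_model, registry_dir = registry_dir), ids)
}

model_metadata <- function(reg) {
  list(label = reg$label, citation = reg$citation,
       calibration = reg$calibration, type = reg$type)
}

# ---- empirical builders ----------------------------------------------------

build_atkinson <- function(registry_dir = NULL) {
  reg <- load_model_registry("atkinson2006", registry_dir)
  pars <- list(
    juvenile = load_parameter_set("atkinson2006", "dgr", "juvenile",
                                  registry_dir),
    "all krill" = load_parameter_set("atkinson2006", "dgr", "all krill",
                                     registry_dir))
  rate <- function(length, sst, chl, photoperiod = NULL, date = NULL,
                   config = list()) {
    atkinson_dgr(length, sst, chl, pars[[stage_select(length, "atkinson2006")]])
  }
  new_krill_model(
    id = "atkinson2006", label = reg$label, type = "empirical",
    requires = c("sst", "chl"), metadata = model_metadata(reg),
    moult_based = FALSE,
    init = function(length, env1, config)
      list(length = length, stage = stage_select(length, "atkinson2006")),
    rate = rate,
    deriv = function(length, env, date, config)
      rate(length, env$sst, env$chl))
}

# shared skeleton of the two moult-based composites
build_composite <- function(id, registry_dir, imp_fn, gi_stage_for,
                            food_scaling = 1) {
  reg <- load_model_registry(id, registry_dir)
  gi_pars <- stats::setNames(
    lapply(KRILL_STAGES[c(1, 4, 2)], function(s)
      load_parameter_set("atkinson2006", "increment", s, registry_dir)),
    KRILL_STAGES[c(1, 4, 2)])
  dgr_fn <- function(length, sst, chl, imp_days, stage) {
    gi <- atkinson_increment(length, sst, chl * food_scaling,
                             gi_pars[[gi_stage_for(length)]])
    gi / imp_days
  }
  rate <- function(length, sst, chl, photoperiod = NULL, date = NULL,
                   config = list()) {
    # constant-forcing limit: IMP-mean conditions equal the point values
    imp <- imp_fn(sst, length, stage_select(length, id))
    dgr_fn(length, sst, chl, imp, NULL)
  }
  new_krill_model(
    id = id, label = reg$label, type = "empirical",
    requires = c("sst", "chl"), metadata = model_metadata(reg),
    moult_based = TRUE,
    init = function(length, env1, config) {
      stage <- stage_select(length, id)
      list(length = length, stage = stage,
           clock = moult_clock(imp_fn(env1$sst, length, stage)),
           moulted = FALSE, last_imp = NA_real_)
    },
    rate = rate, imp_fn = imp_fn, dgr_fn = dgr_fn)
}

build_wiedenmann <- function(registry_dir = NULL) {
  kpars <- load_parameter_set("kawaguchi2006", "imp", "all krill",
                              registry_dir)
  cfg <- load_parameter_set("wiedenmann2008", "composite", "all krill",
                            registry_dir)
  build_composite(
    "wiedenmann2008", registry_dir,
    imp_fn = function(sst, length, stage) kawaguchi_imp(sst, kpars),
    gi_stage_for = function(length) if (length < 35) "juvenile" else "all krill",
    food_scaling = cfg$coefficients[["food_scaling"]])
}

build_tarling <- function(registry_dir = NULL) {
  ipars <- list(
    juvenile = load_parameter_set("tarling2006", "imp", "juvenile",
                                  registry_dir),
    "adult female" = load_parameter_set("tarling2006", "imp", "adult female",
                                        registry_dir))
  build_composite(
    "tarling2006", registry_dir,
    imp_fn = function(sst, length, stage) tarling_imp(sst, length,
                                                      ipars[[stage]]),
    gi_stage_for = function(length) if (length < 35) "juvenile"
                                    else "adult female")
}

# ---- mechanistic builders --------------------------------------------------

build_hofmann_fach <- function(id, registry_dir = NULL) {
  reg <- load_model_registry(id, registry_dir)
  pars <- load_parameter_set(id, "growth", "all krill", registry_dir)
  modifiers <- list(factor = pars$coefficients[["winter_factor"]],
                    window = unlist(reg$winter_window))
  deriv <- function(length, env, date, config) {
    w <- if (is.null(date)) 1 else winter_switch(date, modifiers)
    hofmann_fach_rate(length, env, pars, w)
  }
  rate <- function(length, sst, chl, photoperiod = NULL,
                   date = as.Date("2010-01-15"), config = list()) {
    deriv(length, list(sst = sst, chl = chl, poc = chl_to_poc(chl)), date,
          config)
  }
  new_krill_model(
    id = id, label = reg$label, type = "mechanistic",
    requires = c("sst", "poc"), metadata = model_metadata(reg),
    moult_based = FALSE,
    init = function(length, env1, config)
      list(length = length, stage = stage_select(length, id)),
    rate = rate, deriv = deriv)
}

build_deb <- function(id, variant, registry_dir = NULL) {
  reg <- load_model_registry(id, registry_dir)
  pars <- load_parameter_set(id, "growth", "all krill", registry_dir)
  deriv <- function(length, env, date, config) {
    deb_rate(length, env, pars, variant,
             unlimited_food = isTRUE(config$unlimited_food))
  }
  rate <- function(length, sst, chl, photoperiod = NULL, date = NULL,
                   config = list()) {
    if (variant == "photoperiod" && is.null(photoperiod))
      stop("model '", id, "' requires a photoperiod value")
    deriv(length, list(sst = sst, chl = chl, photoperiod = photoperiod),
          date, config)
  }
  new_krill_model(
    id = id, label = reg$label, type = "mechanistic",
    requires = if (variant == "photoperiod") c("sst", "chl", "photoperiod")
               else c("sst", "chl"),
    metadata = model_metadata(reg), moult_based = FALSE,
    init = function(length, env1, config)
      list(length = length, stage = stage_select(length, id)),
    rate = rate, deriv = deriv)
}

build_ryabov <- function(registry_dir = NULL) {
  reg <- load_model_registry("ryabov2017", registry_dir)
  pars <- load_parameter_set("ryabov2017", "growth", "all krill",
                             registry_dir)
  modifiers <- list(factor = pars$coefficients[["winter_factor"]],
                    window = unlist(reg$winter_window))
  deriv <- function(length, env, date, config) {
    w <- if (is.null(date)) 1 else winter_switch(date, modifiers)
    ryabov_rate(length, env, pars, w)
  }
  rate <- function(length, sst, chl, photoperiod = NULL,
                   date = as.Date("2010-01-15"), config = list()) {
    deriv(length, list(sst = sst, chl = chl), date, config)
  }
  new_krill_model(
    id = "ryabov2017", label = reg$label, type = "mechanistic",
    requires = c("sst", "chl"), metadata = model_metadata(reg),
    moult_based = FALSE,
    init = function(length, env1, config)
      list(length = length, stage = stage_select(length, "ryabov2017")),
    rate = rate, deriv = deriv)
}
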