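# Citation-tagged parameter registry. One structured text file per source
# model; every coefficient block must carry a citation or loading fails.

#' Stage labels recognised by the registry
#' @export
KRILL_STAGES <- c("juvenile", "adult female", "adult male", "all krill")

registry_dir_default <- function() {
  system.file("extdata", "registry", package = "krillgrowth")
}

#' List the model ids present in the registry
#'
#' @param registry_dir directory of registry files (defaults to the
#'   registry shipped with the package).
#' @return character vector of model ids.
#' @export
registry_model_ids <- function(registry_dir = NULL) {
  dir <- if (is.null(registry_dir)) registry_dir_default() else registry_dir
  sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$"))
}

#' Load the raw registry entry for one model
#'
#' @param model_id registry file name without extension.
#' @inheritParams registry_model_ids
#' @return named list with id, label, citation, calibration metadata and
#'   coefficient blocks.
#' @export
load_model_registry <- function(model_id, registry_dir = NULL) {
  dir <- if (is.null(registry_dir)) registry_dir_default() else registry_dir
  path <- file.path(dir, paste0(model_id, ".yaml"))
  if (!file.exists(path)) stop("no registry entry for model '", model_id, "'")
  reg <- yaml::read_yaml(path)
  if (is.null(reg$citation) || !nzchar(reg$citation))
    stop("registry entry '", model_id, "' lacks a citation")
  reg
}

#' Load one citation-tagged coefficient set
#'
#' @param model_id model whose registry file holds the set.
#' @param fn function block within the model entry (e.g. "dgr",
#'   "increment", "imp", "growth").
#' @param stage one of \code{\link{KRILL_STAGES}}.
#' @inheritParams registry_model_ids
#' @return object of class \code{parameter_set} with elements
#'   \code{model}, \code{fn}, \code{stage}, \code{coefficients} (named
#'   numeric), \code{citation} and \code{calibration}.
#' @export
load_parameter_set <- function(model_id, fn, stage = "all krill",
                               registry_dir = NULL) {
  if (!stage %in% KRILL_STAGES)
    stop("unknown stage label '", stage, "'; must be one of: ",
         paste(KRILL_STAGES, collapse = ", "))
  reg <- load_model_registry(model_id, registry_dir)
  blk <- reg$functions[[fn]]
  if (is.null(blk))
    stop("model '", model_id, "' has no '", fn, "' coefficient block")
  st <- blk[[stage]]
  if (is.null(st))
    stop("model '", model_id, "' (", fn, ") has no '", stage,
         "' parameterization")
  if (is.null(st$citation) || !nzchar(st$citation))
    stop("coefficient set ", model_id, "/", fn, "/", stage,
         " lacks a citation")
  co <- unlist(st$coefficients)
  if (is.null(co) || anyNA(suppressWarnings(as.numeric(co))))
    stop("non-numeric or missing coefficients in ", model_id, "/", fn,
         "/", stage)
  structure(list(model = model_id, fn = fn, stage = stage,
                 coefficients = vapply(st$coefficients, as.numeric,
                                       numeric(1)),
                 units = st$units,
                 citation = st$citation,
                 calibration = reg$calibration),
            class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf("<parameter_set> %s / %s / %s\n", x$model, x$fn, x$stage))
  cat("  citation:", x$citation, "\n")
  co <- x$coefficients
  cat(sprintf("  %-14s %s\n", names(co), format(co, digits = 6)), sep = "")
  invisible(x)
}
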