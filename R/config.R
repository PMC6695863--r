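#' Run configuration
#'
#' A YAML file with blocks `domain`, `forcing`, `model`, `ips`,
#' `assimilation`, `experiment`, plus top-level `seed` and `output_dir`.
#' Every key has a default (the standard parameter table for `model`, the
#' 4-arcminute six-layer domain, the 6-h / 30-day window); an empty file is
#' the full default configuration. Unknown keys are rejected by name.
#'
#' @param path path to a YAML configuration file, or `NULL` for pure defaults
#' @return nested list of class `npzd_config` with every key populated
#' @examples
#' cfg <- load_config(NULL)
#' cfg$model$Vm          # 1.0
#' cfg$forcing$days      # 30
#' @export
load_config <- function(path = NULL) {
  defaults <- default_config()
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    if (!is.list(user)) stop("config must be a YAML mapping")
  }
  cfg <- merge_config(defaults, user, "")
  validate_config(cfg)
  class(cfg) <- "npzd_config"
  cfg
}

default_config <- function() {
  list(
    domain = list(
      resolution_arcmin = 4,
      layer_thickness = c(5, 10, 10, 20, 25, 25)),
    forcing = list(
      days = 30, step_hours = 6, current_amplitude = 0.08,
      kh = 50, kv = 1e-4, sst_mean = 24.5, irradiance_max = 400),
    model = list(
      Vm = 1.0, Gm = 0.5, Dp = 0.1, Dz = 0.2, e = 0.05,
      AQ10 = 2.08, BQ10 = 3.10, gamma = 0.75, theta = 0.03,
      Kext = 1.0, Io = 100, wp = 0.73, wd = 1.00, Ks = 1.0, f_ivlev = 0.2,
      n_surface_flux = 0, bio_substeps = 1,
      n_initial = 6, spinup_days = 10),
    ips = list(method = "spline", spacing = 5, radius = NULL),
    assimilation = list(
      max_iterations = 100, ncf_threshold = 5e-4,
      step0 = NULL, step_growth = 1.0, max_halvings = 8),
    experiment = list(
      kind = "IE1", peak = 3.0, floor = 0.5, p_ref = 1.5, slope = 0.2),
    seed = 1,
    output_dir = "."
  )
}

# Recursive merge rejecting unknown keys; NULL defaults accept any scalar.
merge_config <- function(def, user, where) {
  bad <- setdiff(names(user), names(def))
  if (length(bad)) {
    stop(sprintf("unknown config key%s %s%s",
                 if (length(bad) > 1) "s" else "",
                 if (nzchar(where)) paste0("in ", where, ": ") else "",
                 paste(bad, collapse = ", ")))
  }
  for (nm in names(user)) {
    if (is.list(def[[nm]]) && !is.null(names(def[[nm]]))) {
      if (!is.list(user[[nm]])) {
        stop(sprintf("config key %s%s must be a mapping", where, nm))
      }
      def[[nm]] <- merge_config(def[[nm]], user[[nm]],
                                paste0(where, nm, "."))
    } else {
      def[[nm]] <- user[[nm]]
    }
  }
  def
}

validate_config <- function(cfg) {
  num_or_null <- function(x) is.null(x) || (is.numeric(x) && all(is.finite(x)))
  stopifnot(
    is.numeric(cfg$domain$resolution_arcmin),
    is.numeric(cfg$domain$layer_thickness),
    is.numeric(cfg$forcing$days), is.numeric(cfg$forcing$step_hours),
    num_or_null(cfg$ips$radius), num_or_null(cfg$assimilation$step0))
  if (!cfg$ips$method %in% c("spline", "cressman")) {
    stop("ips.method must be 'spline' or 'cressman'")
  }
  if (!cfg$experiment$kind %in% c("IE1", "IE2")) {
    stop("experiment.kind must be 'IE1' or 'IE2'")
  }
  invisible(cfg)
}

# Model-parameter sub-list -> eco_parameters (dropping run-control keys).
config_params <- function(cfg) {
  p <- cfg$model
  p$bio_substeps <- NULL; p$n_initial <- NULL; p$spinup_days <- NULL
  do.call(eco_parameters, p)
}
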