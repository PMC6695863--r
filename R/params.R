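#' Ecological parameters of the NPZD model
#'
#' Returns the 15 ecological constants with their standard defaults:
#' maximum phytoplankton growth rate `Vm` (1.0 /d), maximum zooplankton
#' grazing rate `Gm` (0.5 /d), mortality rates `Dp` (0.1 /d) and `Dz`
#' (0.2 /d), detritus remineralization `e` (0.05 /d), Q10 temperature
#' coefficients `AQ10` (2.08, phytoplankton) and `BQ10` (3.10, zooplankton),
#' zooplankton assimilation ratio `gamma` (0.75), excretion ratio `theta`
#' (0.03), light attenuation `Kext` (1.0 /m), optimum irradiance `Io`
#' (100 W/m^2), sinking speeds `wp` (0.73 m/d, phytoplankton) and `wd`
#' (1.00 m/d, detritus), nutrient half-saturation `Ks` (1.0 mmol/m^3) and
#' Ivlev constant `f_ivlev` (0.2 m^3/(mmol N)).
#'
#' @param ... named overrides of any of the defaults
#' @return named list of class `eco_parameters`
#' @examples
#' p <- eco_parameters(Vm = 1.2)
#' p$Vm; p$Ks
#' @export
eco_parameters <- function(...) {
  p <- list(
    Vm = 1.0, Gm = 0.5, Dp = 0.1, Dz = 0.2, e = 0.05,
    AQ10 = 2.08, BQ10 = 3.10, gamma = 0.75, theta = 0.03,
    Kext = 1.0, Io = 100, wp = 0.73, wd = 1.00, Ks = 1.0, f_ivlev = 0.2,
    n_surface_flux = 0  # river/atmospheric N input, mmol N m-3 d-1, default off
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  validate_eco_parameters(p)
  class(p) <- "eco_parameters"
  p
}

validate_eco_parameters <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                logical(1))
  if (!all(num)) stop("all parameters must be finite scalars")
  if (any(unlist(p) < 0)) stop("all parameters must be non-negative")
  if (p$gamma > 1) stop("gamma must be <= 1")
  if (p$theta > 1) stop("theta must be <= 1")
  if (p$AQ10 <= 0 || p$BQ10 <= 0 || p$Ks <= 0 || p$Io <= 0) {
    stop("AQ10, BQ10, Ks and Io must be positive")
  }
  invisible(p)
}

#' @export
print.eco_parameters <- function(x, ...) {
  cat("<eco_parameters>\n")
  print(unlist(unclass(x)))
  invisible(x)
}
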