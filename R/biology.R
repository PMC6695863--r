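#' Biological process rates of the NPZD model
#'
#' The four-compartment nitrogen cycle couples nutrient N, phytoplankton P,
#' zooplankton Z and detritus D (all mmol N m^-3). Phytoplankton uptake is
#' limited by temperature (Q10 law), nutrient (Michaelis--Menten) and light
#' (Steele curve); zooplankton graze with an Ivlev saturating response and a
#' separate Q10; mortality feeds detritus, detritus remineralizes to N, and
#' the unassimilated grazing fraction is routed to detritus so that the four
#' tendencies sum to zero cellwise when external nitrogen sources are off.
#'
#' @param T_c temperature, deg C
#' @param Q10 temperature coefficient (> 0), referenced to 10 deg C
#' @return `temperature_factor`: Q10^((T-10)/10), dimensionless
#' @examples
#' temperature_factor(20, 2.08)  # 2.08
#' nutrient_limitation(1, 1)     # 0.5
#' light_limitation(100, 100)    # 1
#' @export
temperature_factor <- function(T_c, Q10) {
  if (any(Q10 <= 0)) stop("Q10 must be > 0")
  Q10^((T_c - 10) / 10)
}

#' @rdname temperature_factor
#' @param N nutrient concentration, mmol m^-3 (>= 0)
#' @param Ks half-saturation constant, mmol m^-3 (> 0)
#' @return `nutrient_limitation`: N/(Ks+N) in [0,1)
#' @export
nutrient_limitation <- function(N, Ks) {
  if (any(N < 0)) stop("N must be >= 0")
  if (any(Ks <= 0)) stop("Ks must be > 0")
  N / (Ks + N)
}

#' @rdname temperature_factor
#' @param I irradiance at depth, W m^-2 (>= 0)
#' @param Io optimum irradiance, W m^-2 (> 0)
#' @return `light_limitation`: Steele curve (I/Io) exp(1 - I/Io)
#' @export
light_limitation <- function(I, Io) {
  if (any(I < 0)) stop("I must be >= 0")
  if (any(Io <= 0)) stop("Io must be > 0")
  (I / Io) * exp(1 - I / Io)
}

#' @rdname temperature_factor
#' @param P phytoplankton concentration, mmol N m^-3 (>= 0)
#' @param Gm maximum grazing rate, d^-1
#' @param f_ivlev Ivlev constant, m^3 (mmol N)^-1
#' @param BQ10 zooplankton temperature coefficient
#' @return `grazing_rate`: specific grazing rate per unit zooplankton biomass,
#'   d^-1: Gm (1 - exp(-f P)) Q10 factor
#' @export
grazing_rate <- function(P, Gm, f_ivlev, T_c, BQ10) {
  if (any(P < 0)) stop("P must be >= 0")
  Gm * (1 - exp(-f_ivlev * P)) * temperature_factor(T_c, BQ10)
}

#' Cellwise biological tendencies
#'
#' @param state list with numeric vectors `N`, `P`, `Z`, `D` (mmol N m^-3,
#'   all >= 0, same length)
#' @param T_c temperature, deg C (scalar or vector)
#' @param I irradiance at the cell's depth, W m^-2 (scalar or vector)
#' @param params an [eco_parameters()] object
#' @param surface logical vector flagging surface cells (external N input, if
#'   configured, enters only there)
#' @return list of tendencies `dN`, `dP`, `dZ`, `dD` in mmol N m^-3 d^-1
#' @export
biological_tendencies <- function(state, T_c, I, params, surface = FALSE) {
  N <- state$N; P <- state$P; Z <- state$Z; D <- state$D
  if (any(N < 0 | P < 0 | Z < 0 | D < 0)) stop("state must be non-negative")
  tfA <- temperature_factor(T_c, params$AQ10)
  tfB <- temperature_factor(T_c, params$BQ10)
  U <- params$Vm * tfA * nutrient_limitation(N, params$Ks) *
    light_limitation(I, params$Io) * P
  G <- params$Gm * (1 - exp(-params$f_ivlev * P)) * tfB * Z
  src <- params$n_surface_flux * as.numeric(surface)
  list(
    dN = -U + params$theta * G + params$e * D + src,
    dP = U - G - params$Dp * P,
    dZ = params$gamma * G - params$theta * G - params$Dz * Z,
    dD = (1 - params$gamma) * G + params$Dp * P + params$Dz * Z - params$e * D
  )
}

# One forward-Euler biology step (dt_days) with conservative clipping:
# negative P/Z/D are clipped to zero with the deficit taken from N; a then
# negative N is clipped to zero (non-conservative, logged). Returns the new
# state plus the clipped-N mass removed (for diagnostics).
# Positivity of inputs is the caller's responsibility (post-clip states are).
bio_step <- function(state, T_c, I, params, dt_days, surface = FALSE) {
  td <- biological_tendencies(state, T_c, I, params, surface)
  N <- state$N + dt_days * td$dN
  P <- state$P + dt_days * td$dP
  Z <- state$Z + dt_days * td$dZ
  D <- state$D + dt_days * td$dD
  negP <- pmin(P, 0); negZ <- pmin(Z, 0); negD <- pmin(D, 0)
  P <- P - negP; Z <- Z - negZ; D <- D - negD
  N <- N + negP + negZ + negD
  negN <- pmin(N, 0)
  N <- N - negN
  list(N = N, P = P, Z = Z, D = D, clipped_n = -sum(negN))
}

# Adjoint of bio_step: given adjoint variables (lN,lP,lZ,lD) of the outputs
# and the INPUT state, return adjoints of the inputs. Exact transpose of the
# linearization of the discrete step, including the clipping branches
# (subgradient 0/1 at the kink).
bio_step_adjoint <- function(lam, state, T_c, I, params, dt_days,
                             surface = FALSE) {
  N <- state$N; P <- state$P; Z <- state$Z; D <- state$D
  tfA <- temperature_factor(T_c, params$AQ10)
  tfB <- temperature_factor(T_c, params$BQ10)
  nut <- N / (params$Ks + N)
  lig <- light_limitation(I, params$Io)
  # recompute raw Euler outputs to locate the clipping branches
  td <- biological_tendencies(state, T_c, I, params, surface)
  rN <- N + dt_days * td$dN; rP <- P + dt_days * td$dP
  rZ <- Z + dt_days * td$dZ; rD <- D + dt_days * td$dD
  cN <- rN + pmin(rP, 0) + pmin(rZ, 0) + pmin(rD, 0)

  lN <- lam$N; lP <- lam$P; lZ <- lam$Z; lD <- lam$D
  # reverse N-clip: output N = max(cN, 0)
  lN <- lN * as.numeric(cN >= 0)
  # reverse P/Z/D clip: X_out = max(rX,0), N gains min(rX,0)
  lrP <- lP * as.numeric(rP >= 0) + lN * as.numeric(rP < 0)
  lrZ <- lZ * as.numeric(rZ >= 0) + lN * as.numeric(rZ < 0)
  lrD <- lD * as.numeric(rD >= 0) + lN * as.numeric(rD < 0)
  lrN <- lN

  # Jacobian of the tendencies wrt (N,P,Z,D)
  dU_dN <- params$Vm * tfA * lig * P * params$Ks / (params$Ks + N)^2
  dU_dP <- params$Vm * tfA * lig * nut
  dG_dP <- params$Gm * tfB * params$f_ivlev * exp(-params$f_ivlev * P) * Z
  dG_dZ <- params$Gm * tfB * (1 - exp(-params$f_ivlev * P))
  th <- params$theta; ga <- params$gamma

  # transpose of I + dt J applied to (lrN, lrP, lrZ, lrD)
  aN <- lrN + dt_days * (-dU_dN * lrN + dU_dN * lrP)
  aP <- lrP + dt_days * (
    (-dU_dP + th * dG_dP) * lrN +
    (dU_dP - dG_dP - params$Dp) * lrP +
    (ga - th) * dG_dP * lrZ +
    ((1 - ga) * dG_dP + params$Dp) * lrD)
  aZ <- lrZ + dt_days * (
    th * dG_dZ * lrN +
    (-dG_dZ) * lrP +
    ((ga - th) * dG_dZ - params$Dz) * lrZ +
    ((1 - ga) * dG_dZ + params$Dz) * lrD)
  aD <- lrD + dt_days * (params$e * lrN - params$e * lrD)
  list(N = aN, P = aP, Z = aZ, D = aD)
}
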