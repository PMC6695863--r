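#' Evaluation metrics: MAE, RMSE, similarity coefficient, normalized cost
#'
#' All metrics run over the `m` grids with observations: the mean absolute
#' error `MAE = (1/m) sum |X_mod - X_obs|`, the root-mean-square error
#' `RMSE = sqrt((1/m) sum (X_mod - X_obs)^2)` (always >= MAE), and the
#' similarity coefficient
#' `SC = 1 - (2/pi) arccos( sum X_mod X_obs / sqrt(sum X_mod^2 sum X_obs^2) )`,
#' the normalized angle between the two vectors: 1 for proportional fields,
#' 0 for orthogonal ones, invariant to positive rescaling of either input.
#'
#' @param x_mod,x_obs numeric vectors of equal length (model results and
#'   observations); `NA` pairs are dropped
#' @return scalar metric value
#' @examples
#' mae(c(1, 2), c(1, 3))                    # 0.5
#' rmse(c(1, 2), c(1, 3))                   # sqrt(0.5)
#' similarity_coefficient(c(1, 0), c(1, 1)) # 0.5
#' @export
mae <- function(x_mod, x_obs) {
  p <- metric_pair(x_mod, x_obs)
  mean(abs(p$mod - p$obs))
}

#' @rdname mae
#' @export
rmse <- function(x_mod, x_obs) {
  p <- metric_pair(x_mod, x_obs)
  sqrt(mean((p$mod - p$obs)^2))
}

#' @rdname mae
#' @export
similarity_coefficient <- function(x_mod, x_obs) {
  p <- metric_pair(x_mod, x_obs)
  nm <- sqrt(sum(p$mod^2)); no <- sqrt(sum(p$obs^2))
  if (nm == 0 || no == 0) stop("similarity coefficient needs non-zero vectors")
  cosang <- sum(p$mod * p$obs) / (nm * no)
  1 - (2 / pi) * acos(min(1, max(-1, cosang)))
}

metric_pair <- function(x_mod, x_obs) {
  x_mod <- as.numeric(x_mod); x_obs <- as.numeric(x_obs)
  if (length(x_mod) != length(x_obs)) stop("inputs must have equal length")
  ok <- is.finite(x_mod) & is.finite(x_obs)
  if (!any(ok)) stop("no observed grids (m = 0)")
  list(mod = x_mod[ok], obs = x_obs[ok])
}

#' @rdname mae
#' @param j_history numeric vector of cost values per iteration,
#'   `j_history[1] > 0`
#' @return `ncf_series`: `j_history / j_history[1]`, starting at 1
#' @export
ncf_series <- function(j_history) {
  if (length(j_history) < 1 || j_history[1] <= 0) {
    stop("j_history[1] must be > 0")
  }
  j_history / j_history[1]
}

#' Bundle all metrics for a model/observation pair
#'
#' @inheritParams mae
#' @param j_history optional cost history for the NCF entry
#' @return list of class `metric_bundle`: `ncf` (final normalized cost, NA
#'   if no history), `mae`, `rmse`, `sc`, `m` (number of observed grids)
#' @export
metric_bundle <- function(x_mod, x_obs, j_history = NULL) {
  p <- metric_pair(x_mod, x_obs)
  structure(list(
    ncf = if (is.null(j_history)) NA_real_ else
      utils::tail(ncf_series(j_history), 1),
    mae = mae(p$mod, p$obs), rmse = rmse(p$mod, p$obs),
    sc = similarity_coefficient(p$mod, p$obs),
    m = length(p$mod)), class = "metric_bundle")
}

#' @export
print.metric_bundle <- function(x, ...) {
  cat(sprintf("<metric_bundle> NCF %.3e  MAE %.4f  RMSE %.4f  SC %.3f  (m = %d)\n",
              x$ncf, x$mae, x$rmse, x$sc, x$m))
  invisible(x)
}

#' Chlorophyll-a to carbon to nitrogen conversions
#'
#' Surface chlorophyll-a (mg m^-3) converts to phytoplankton carbon
#' (mg C m^-3) through the saturating carbon-to-chlorophyll ratio
#' `C = rho_max * chl/(chl + K_half) * chl` with `rho_max = 90` and
#' `K_half = 0.477`; carbon then converts to nitrogen concentration through
#' the Redfield ratio (106 mol C : 16 mol N) and the atomic mass of carbon
#' (12.011 g/mol). An alternative reading of the carbon relation,
#' `C = rho_max * chl/(chl + K_half)` (a bounded ratio rather than a
#' saturating product), is available via `form = "ratio"`.
#'
#' @param chla chlorophyll-a, mg m^-3 (>= 0)
#' @param rho_max maximum carbon-to-chlorophyll ratio (default 90)
#' @param k_half half-saturation coefficient, mg m^-3 (default 0.477)
#' @param form `"product"` (default) or `"ratio"` (see Details)
#' @return `chla_to_carbon`: carbon, mg C m^-3
#' @examples
#' chla_to_carbon(0.477)                  # 21.465
#' carbon_to_nitrogen(12.011 * 106)       # 16
#' @export
chla_to_carbon <- function(chla, rho_max = 90, k_half = 0.477,
                           form = c("product", "ratio")) {
  form <- match.arg(form)
  if (any(chla < 0, na.rm = TRUE)) stop("chla must be >= 0")
  ratio <- chla / (chla + k_half)
  ratio[chla == 0] <- 0
  switch(form,
         product = rho_max * ratio * chla,
         ratio = rho_max * ratio)
}

#' @rdname chla_to_carbon
#' @param carbon carbon concentration, mg C m^-3 (>= 0)
#' @return `carbon_to_nitrogen`: nitrogen concentration, mmol N m^-3
#' @export
carbon_to_nitrogen <- function(carbon) {
  if (any(carbon < 0, na.rm = TRUE)) stop("carbon must be >= 0")
  (carbon / 12.011) * (16 / 106)
}
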