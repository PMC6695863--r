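#' Prescribed "truth" phytoplankton fields for twin experiments
#'
#' `truth_ie1` prescribes a paraboloid of revolution in lon/lat: concentration
#' rises from `floor` at the central-basin centroid to `peak` at the wet cell
#' farthest from it (the bay heads), mimicking a sea polluted in its three
#' bays and cleaner in the middle. `truth_ie2` instead makes the surface
#' pattern an affine function of the time-mean sea-surface temperature,
#' clipped at zero.
#'
#' Subsurface values attenuate the surface pattern by `exp(-z/20 m)` at layer
#' mid-depth; this style of twin experiment only constrains the surface map.
#'
#' @param grid an `npzd_grid`
#' @param peak,floor surface concentration extremes, mmol N m^-3
#'   (defaults 3.0 and 0.5)
#' @return object of class `npzd_truth`: list with `surface` (nx x ny matrix,
#'   NA on land), `field` (packed active-cell vector over the 3-D grid) and
#'   `label`.
#' @examples
#' g <- bohai_grid(resolution_arcmin = 20)
#' tr <- truth_ie1(g)
#' range(tr$surface, na.rm = TRUE)   # floor .. peak
#' @export
truth_ie1 <- function(grid, peak = 3.0, floor = 0.5) {
  stopifnot(inherits(grid, "npzd_grid"))
  if (!(peak > floor) || floor < 0) stop("need peak > floor >= 0")
  ctr <- basin_centroid(grid)
  lon_c <- grid$lon[ctr[1]]; lat_c <- grid$lat[ctr[2]]
  LON <- matrix(grid$lon, grid$nx, grid$ny)
  LAT <- matrix(grid$lat, grid$nx, grid$ny, byrow = TRUE)
  r2 <- (LON - lon_c)^2 + (LAT - lat_c)^2
  r2max <- max(r2[grid$mask])
  surf <- floor + (peak - floor) * r2 / r2max
  surf[!grid$mask] <- NA_real_
  new_truth(grid, surf, "IE1")
}

#' @rdname truth_ie1
#' @param forcing an `npzd_forcing` covering the grid (its SST drives the
#'   pattern)
#' @param p_ref concentration at the domain-mean SST, mmol N m^-3 (default 1.5)
#' @param slope concentration change per deg C (default 0.2)
#' @export
truth_ie2 <- function(grid, forcing, p_ref = 1.5, slope = 0.2) {
  stopifnot(inherits(grid, "npzd_grid"), inherits(forcing, "npzd_forcing"))
  sst_mean <- apply(forcing$sst, c(1, 2), mean)
  t0 <- mean(sst_mean[grid$mask])
  surf <- pmax(0, p_ref + slope * (sst_mean - t0))
  surf[!grid$mask] <- NA_real_
  new_truth(grid, surf, "IE2")
}

# Attach the exp(-z/20) vertical profile and pack to active cells.
new_truth <- function(grid, surf, label) {
  field <- surface_to_column(grid, surf)
  tr <- list(surface = surf, field = field, label = label)
  class(tr) <- "npzd_truth"
  tr
}

#' Expand a surface pattern down the water column
#'
#' Applies the standard subsurface attenuation `exp(-z_mid / 20)` (z_mid =
#' layer mid-depth, m) to a surface field and packs the result over active
#' cells. The same expansion links the assimilation control (a surface field)
#' to the full 3-D initial phytoplankton state, so truth and control live in
#' the same space.
#'
#' @param grid an `npzd_grid`
#' @param surf nx x ny surface matrix (NA on land is fine)
#' @return packed active-cell vector (mmol N m^-3)
#' @export
surface_to_column <- function(grid, surf) {
  w <- vertical_profile(grid)
  a <- array(0, c(grid$nx, grid$ny, grid$nz))
  s <- surf; s[!grid$mask] <- 0; s[is.na(s)] <- 0
  for (k in seq_len(grid$nz)) a[, , k] <- s * w[k]
  pack3(grid, a)
}

# Per-layer attenuation weights of the vertical profile.
vertical_profile <- function(grid) exp(-grid$layer_mid / 20)

#' @export
print.npzd_truth <- function(x, ...) {
  cat(sprintf("<npzd_truth %s> surface range %.3f .. %.3f mmol N m-3\n",
              x$label, min(x$surface, na.rm = TRUE), max(x$surface, na.rm = TRUE)))
  invisible(x)
}
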