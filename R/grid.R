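#' Model grid for the idealized Bohai Sea domain
#'
#' Builds the structured lon/lat grid spanning 37--41 N, 117.5--122.5 E with a
#' layered vertical discretization. The land/sea mask and bathymetry come from
#' a built-in idealized Bohai geometry (a central elliptical basin plus three
#' bay lobes standing in for Liaodong, Bohai and Laizhou Bays) or from a
#' user-supplied bathymetry matrix.
#'
#' Columns truncate at the local bathymetry: a layer is active in a wet cell
#' when its top lies above the seabed, and the bottom active layer may be a
#' partial cell. Every wet cell has at least one active layer.
#'
#' @param resolution_arcmin horizontal grid spacing in arc-minutes; must divide
#'   the 5 degree x 4 degree extent into whole cells. Default 4 (the 4' x 4'
#'   configuration).
#' @param layer_thickness vertical layer thicknesses in meters, surface to
#'   bottom. Default `c(5, 10, 10, 20, 25, 25)` (six layers, 95 m total).
#' @param bathymetry optional numeric matrix (nx x ny) of water depth in
#'   meters; `NA` or values `<= 0` mark land. When `NULL` the idealized
#'   geometry is used.
#' @return an object of class `npzd_grid`: a list with cell-center coordinates
#'   (`lon`, `lat`), edges, counts (`nx`, `ny`, `nz`), `layer_thickness`,
#'   logical `mask`, `depth` (m, `NA` on land), per-column active layer count
#'   `nlay`, metric factors (`dx` per latitude row, `dy`, `area`), and the
#'   packed active-cell indexing used by the solver.
#' @examples
#' g <- bohai_grid()
#' g$nx; g$ny          # 75 x 60 at 4'
#' sum(g$mask)         # wet columns
#' @export
bohai_grid <- function(resolution_arcmin = 4,
                       layer_thickness = c(5, 10, 10, 20, 25, 25),
                       bathymetry = NULL) {
  if (!is.numeric(resolution_arcmin) || length(resolution_arcmin) != 1L ||
      resolution_arcmin <= 0) {
    stop("resolution_arcmin must be a positive scalar")
  }
  if (any(!is.finite(layer_thickness)) || any(layer_thickness <= 0)) {
    stop("layer_thickness must be strictly positive")
  }
  lon0 <- 117.5; lon1 <- 122.5; lat0 <- 37; lat1 <- 41
  res_deg <- resolution_arcmin / 60
  nx <- (lon1 - lon0) / res_deg
  ny <- (lat1 - lat0) / res_deg
  if (abs(nx - round(nx)) > 1e-9 || abs(ny - round(ny)) > 1e-9) {
    stop("resolution_arcmin must divide the 5 x 4 degree extent into whole cells")
  }
  nx <- as.integer(round(nx)); ny <- as.integer(round(ny))
  lon_edges <- seq(lon0, lon1, length.out = nx + 1L)
  lat_edges <- seq(lat0, lat1, length.out = ny + 1L)
  lon <- (lon_edges[-1L] + lon_edges[-(nx + 1L)]) / 2
  lat <- (lat_edges[-1L] + lat_edges[-(ny + 1L)]) / 2

  if (is.null(bathymetry)) {
    depth <- idealized_bohai_depth(lon, lat)
    # the idealized sea is enclosed: keep the outermost cell ring dry so no
    # open-boundary cell exists and the basin conserves mass exactly
    depth[c(1, nx), ] <- NA_real_
    depth[, c(1, ny)] <- NA_real_
  } else {
    if (!is.matrix(bathymetry) || nrow(bathymetry) != nx || ncol(bathymetry) != ny) {
      stop(sprintf("bathymetry must be a %d x %d matrix", nx, ny))
    }
    depth <- bathymetry
    depth[!is.finite(depth) | depth <= 0] <- NA_real_
  }
  mask <- is.finite(depth)
  depth[!mask] <- NA_real_
  if (!any(mask)) stop("mask has no wet cells")

  nz <- length(layer_thickness)
  layer_top <- cumsum(c(0, layer_thickness))[seq_len(nz)]
  layer_mid <- layer_top + layer_thickness / 2

  # active layer count per column: layers with at least min_dz of water above
  # the seabed (slivers thinner than that are merged into the bathymetry so
  # no near-zero cell volume can break the explicit transport step)
  min_dz <- 1.5
  nlay <- matrix(0L, nx, ny)
  nlay[mask] <- vapply(depth[mask],
                       function(d) sum(layer_top + min_dz <= d), integer(1))
  nlay[mask & nlay == 0L] <- 1L  # every wet cell keeps >= 1 active layer

  # metric factors (spherical earth, cell-centered)
  r_earth <- 6371000
  dy <- r_earth * (pi / 180) * res_deg
  dx_row <- r_earth * cos(lat * pi / 180) * (pi / 180) * res_deg  # per lat row
  area <- outer(rep(1, nx), dx_row) * dy  # nx x ny

  # per-cell layer thickness with partial bottom cell
  act <- array(FALSE, c(nx, ny, nz))
  dz3 <- array(0, c(nx, ny, nz))
  for (k in seq_len(nz)) {
    a <- mask & (nlay >= k)
    act[, , k] <- a
    dzk <- pmin(layer_thickness[k], depth - layer_top[k])
    dzk[!a] <- 0
    # a single-layer wet cell shallower than the first layer keeps its depth
    dzk[a & dzk <= 0] <- depth[a & dzk <= 0]
    dz3[, , k] <- ifelse(a, dzk, 0)
  }

  pidx <- which(act)                      # packed active-cell order
  lookup <- array(NA_integer_, c(nx, ny, nz))
  lookup[pidx] <- seq_along(pidx)
  vol <- (array(area, c(nx, ny, nz)) * dz3)[pidx]

  g <- list(
    lon = lon, lat = lat, lon_edges = lon_edges, lat_edges = lat_edges,
    nx = nx, ny = ny, nz = nz,
    resolution_arcmin = resolution_arcmin,
    layer_thickness = layer_thickness, layer_top = layer_top,
    layer_mid = layer_mid,
    mask = mask, depth = depth, nlay = nlay,
    dx = dx_row, dy = dy, area = area,
    act = act, dz3 = dz3, pidx = pidx, lookup = lookup, vol = vol,
    npack = length(pidx),
    surface_pack = lookup[, , 1][mask]    # packed positions of surface wet cells
  )
  class(g) <- "npzd_grid"
  g
}

# Idealized Bohai bathymetry: central elliptical basin plus three bay lobes.
# Depth in meters at cell centers; NA on land. The basin deepens to ~70 m at
# its centroid; the bays are shallow (<= ~20 m). The sea is fully enclosed
# (the strait is treated as closed) so the default basin conserves mass.
idealized_bohai_depth <- function(lon, lat) {
  shapes <- list(
    basin    = list(c(120.2, 38.9), c(1.60, 1.30), 65, "basin"),
    liaodong = list(c(121.3, 40.3), c(1.00, 0.90), 15, "bay"),
    bohaibay = list(c(118.2, 38.7), c(0.90, 0.80), 15, "bay"),
    laizhou  = list(c(119.6, 37.4), c(0.90, 0.70), 15, "bay")
  )
  nx <- length(lon); ny <- length(lat)
  depth <- matrix(NA_real_, nx, ny)
  LON <- matrix(lon, nx, ny); LAT <- matrix(lat, nx, ny, byrow = TRUE)
  for (s in shapes) {
    r2 <- ((LON - s[[1]][1]) / s[[2]][1])^2 + ((LAT - s[[1]][2]) / s[[2]][2])^2
    inside <- r2 < 1
    d <- 5 + s[[3]] * pmax(0, 1 - r2)
    depth[inside] <- pmax(depth[inside], d[inside], na.rm = TRUE)
  }
  depth
}

#' Centroid (cell indices) of the idealized central basin
#'
#' Used by the paraboloid truth field as its vertex. Returns the wet cell whose
#' center is closest to the deepest point of the idealized basin.
#' @param grid an `npzd_grid`
#' @return integer vector `c(i, j)`
#' @keywords internal
basin_centroid <- function(grid) {
  target <- c(120.2, 38.9)
  wet <- which(grid$mask, arr.ind = TRUE)
  d2 <- (grid$lon[wet[, 1]] - target[1])^2 + (grid$lat[wet[, 2]] - target[2])^2
  as.integer(wet[which.min(d2), ])
}

#' @export
print.npzd_grid <- function(x, ...) {
  cat(sprintf(
    "<npzd_grid> %d x %d cells (%g'), %d layers (%g m), %d wet columns, %d active cells\n",
    x$nx, x$ny, x$resolution_arcmin, x$nz, sum(x$layer_thickness),
    sum(x$mask), x$npack))
  invisible(x)
}

# Pack a full 3-D (nx,ny,nz) array to the active-cell vector.
pack3 <- function(grid, a) a[grid$pidx]

# Expand a packed vector to a full 3-D array (0 or NA elsewhere).
unpack3 <- function(grid, v, fill = NA_real_) {
  a <- array(fill, c(grid$nx, grid$ny, grid$nz))
  a[grid$pidx] <- v
  a
}

# Surface-layer matrix (nx,ny) from a packed vector.
surface_field <- function(grid, v, fill = NA_real_) {
  m <- matrix(fill, grid$nx, grid$ny)
  m[grid$mask] <- v[grid$surface_pack]
  m
}
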