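test_that("point selection covers the lattice, snapped to wet cells", {
  g <- coarse_grid()
  sel <- select_independent_points(g, spacing = 1)
  expect_equal(nrow(sel$points), sum(g$mask))  # spacing 1: every wet cell
  sel5 <- select_independent_points(g, spacing = 5)
  expect_true(all(g$mask[sel5$points]))        # never on a dry cell
  # all-wet 10 x 10 sub-block logic: ceil(10/5)^2 lattice nodes
  bath <- matrix(NA_real_, 10, 8)
  bath[2:9, 2:7] <- 20
  gw <- bohai_grid(30, layer_thickness = c(5, 10), bathymetry = bath)
  s2 <- select_independent_points(gw, spacing = 5)
  expect_equal(length(s2$lattice$xi) * length(s2$lattice$yj), 4)
})

test_that("cressman weights follow (R^2-d^2)/(R^2+d^2) with normalization", {
  g <- coarse_grid()
  ips <- independent_points(g, spacing = 4, method = "cressman", radius = 10)
  K <- ips$kappa
  expect_true(all(K >= 0 & K <= 1))
  expect_equal(rowSums(K), rep(1, nrow(K)), tolerance = 1e-12)
  # a cell coincident with a point takes weight 1 there
  wet <- which(g$mask, arr.ind = TRUE)
  wet_row <- function(ij) which(wet[, 1] == ij[1] & wet[, 2] == ij[2])
  r1 <- wet_row(ips$points[1, ])
  expect_equal(unname(K[r1, 1]), 1)
  # raw weight formula at d = 3, R = 5
  expect_equal((25 - 9) / (25 + 9), 16 / 34)
  # two points at equal distance share the weight equally
  gsub <- tiny_grid()
  p2 <- matrix(c(2L, 2L, 4L, 2L), 2, 2, byrow = TRUE)
  Keq <- cressman_kappa(p2, gsub, radius = 5)
  wet2 <- which(gsub$mask, arr.ind = TRUE)
  mid <- which(wet2[, 1] == 3 & wet2[, 2] == 2)
  expect_equal(unname(Keq[mid, ]), c(0.5, 0.5))
})

test_that("cells beyond the radius fall back to their nearest point", {
  bath <- matrix(20, 10, 8)
  g <- bohai_grid(resolution_arcmin = 30, layer_thickness = c(5, 10),
                  bathymetry = bath)
  pts <- matrix(c(1L, 1L, 10L, 8L), 2, 2, byrow = TRUE)
  K <- cressman_kappa(pts, g, radius = 2)
  wet <- which(g$mask, arr.ind = TRUE)
  far <- which(wet[, 1] == 5 & wet[, 2] == 4)  # out of range of both
  expect_equal(sum(K[far, ] == 1), 1)
  expect_equal(sum(K[far, ]), 1)
})

test_that("spline expansion is exact on constants, planes and cubics", {
  g <- bohai_grid(resolution_arcmin = 12, bathymetry = matrix(20, 25, 20))
  ips <- independent_points(g, spacing = 4, method = "spline")
  wet <- which(g$mask, arr.ind = TRUE)
  # constants
  cst <- ips_expand(ips, rep(2.5, nrow(ips$points)))
  expect_equal(cst, rep(2.5, nrow(wet)), tolerance = 1e-12)
  # plane a + b i + c j
  plane <- function(i, j) 1 + 0.3 * i - 0.2 * j
  pv <- plane(ips$points[, 1], ips$points[, 2])
  expect_equal(ips_expand(ips, pv), plane(wet[, 1], wet[, 2]),
               tolerance = 1e-10)
  # cubic in one index
  cub <- function(i, j) 0.5 + 0.01 * (i - 10)^3
  cv <- cub(ips$points[, 1], ips$points[, 2])
  expect_equal(ips_expand(ips, cv), cub(wet[, 1], wet[, 2]),
               tolerance = 1e-8)
})

test_that("expansion is linear and matches the brute-force weight sum", {
  g <- coarse_grid()
  for (m in c("spline", "cressman")) {
    ips <- independent_points(g, spacing = 4, method = m)
    set.seed(21)
    x <- rnorm(nrow(ips$points)); y <- rnorm(nrow(ips$points))
    lin <- ips_expand(ips, 2 * x + 3 * y)
    expect_equal(lin, 2 * ips_expand(ips, x) + 3 * ips_expand(ips, y),
                 tolerance = 1e-12)
    # naive double loop over the weight sum
    naive <- numeric(nrow(ips$kappa))
    for (r in seq_len(nrow(ips$kappa))) {
      acc <- 0
      for (n in seq_len(ncol(ips$kappa))) acc <- acc + ips$kappa[r, n] * x[n]
      naive[r] <- acc
    }
    expect_equal(ips_expand(ips, x), naive, tolerance = 1e-12)
  }
})

test_that("projection is the exact transpose of the expansion", {
  g <- coarse_grid()
  ips <- independent_points(g, spacing = 5, method = "spline")
  set.seed(31)
  x <- rnorm(nrow(ips$points))
  y <- rnorm(nrow(ips$kappa))
  lhs <- sum(ips_expand(ips, x) * y)
  rhs <- sum(x * project_to_independent_points(ips, y))
  expect_equal(lhs, rhs, tolerance = 1e-12 * max(1, abs(lhs)))
  # explicit double-loop transpose
  gproj <- project_to_independent_points(ips, y)
  naive <- numeric(ncol(ips$kappa))
  for (n in seq_len(ncol(ips$kappa))) {
    naive[n] <- sum(ips$kappa[, n] * y)
  }
  expect_equal(gproj, naive, tolerance = 1e-12)
  # identity kappa (spacing 1 on an all-wet grid) passes gradients through
  bath <- matrix(20, 10, 8)
  gi <- bohai_grid(30, bathymetry = bath)
  ipsi <- independent_points(gi, spacing = 1, method = "cressman")
  gg <- rnorm(sum(gi$mask))
  ord <- order(ipsi$points[, 2], ipsi$points[, 1])
  expect_equal(project_to_independent_points(ipsi, gg)[ord], gg,
               tolerance = 1e-12)
})

test_that("interpolation demo: spline beats Cressman on the smooth surface", {
  g <- coarse_grid()
  demo <- interp_demo(g, spacing = 3)
  st <- demo$stats
  expect_lt(st$rmse[st$method == "spline"], st$rmse[st$method == "cressman"])
  # spacing 1 on an all-wet grid reproduces the surface exactly
  bath <- matrix(20, 10, 8)
  gi <- bohai_grid(30, bathymetry = bath)
  d1 <- interp_demo(gi, spacing = 1)
  expect_lt(max(d1$stats$rmse), 1e-10)
})
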