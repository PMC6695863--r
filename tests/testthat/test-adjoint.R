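test_that("cost function matches its discrete definition", {
  g <- tiny_grid()
  f <- tiny_forcing()
  tr <- run_forward(g, f, eco_parameters(), tiny_init(), days = 2)
  obs <- observations_from_trajectory(tr)
  expect_equal(cost_function(tr, obs), 0)    # P = P_o everywhere
  # one observed point, difference 2 -> J = 2
  o1 <- observation_set(matrix(3), weights = matrix(1), times = 1L)
  expect_equal(cost_function(matrix(5, 1, 1), o1), 2)
  # random fields against an element-by-element summation oracle
  set.seed(51)
  P <- matrix(runif(40), 8, 5)
  V <- matrix(runif(40), 8, 5)
  W <- matrix(rbinom(40, 1, 0.6), 8, 5)
  obs2 <- observation_set(V, W)
  acc <- 0
  for (i in 1:8) for (t in 1:5) acc <- acc + W[i, t] * (P[i, t] - V[i, t])^2
  expect_equal(cost_function(P, obs2), acc / 2, tolerance = 1e-12)
  expect_error(observation_set(V, W * 2), "0 or 1")
})

test_that("adjoint gradient matches central finite differences to 1e-6", {
  g <- tiny_grid()       # 5 x 4 columns, 2 layers, 38 active cells
  f <- tiny_forcing()
  p <- eco_parameters()
  init0 <- tiny_init()
  tr <- run_forward(g, f, p, init0, days = 1, store = TRUE)  # 4 steps
  set.seed(52)
  obs <- observation_set(tr$surface_P +
    matrix(rnorm(length(tr$surface_P), 0, 0.3), nrow(tr$surface_P)))
  grad <- adjoint_sweep(tr, obs, g, f, p)
  runJ <- function(Pv) {
    i <- init0; i$P <- Pv
    cost_function(run_forward(g, f, p, i, days = 1), obs)
  }
  h <- 1e-5
  for (i in seq_len(g$npack)) {
    e <- numeric(g$npack); e[i] <- h
    fd <- (runJ(init0$P + e) - runJ(init0$P - e)) / (2 * h)
    expect_lt(abs(fd - grad$P[i]) / max(abs(fd), 1e-10), 1e-6)
  }
})

test_that("zero misfit gives a zero gradient", {
  g <- tiny_grid()
  f <- tiny_forcing()
  p <- eco_parameters()
  tr <- run_forward(g, f, p, tiny_init(), days = 1, store = TRUE)
  grad <- adjoint_sweep(tr, observations_from_trajectory(tr), g, f, p)
  expect_equal(grad$P, numeric(g$npack))
  expect_equal(grad$N, numeric(g$npack))
})

test_that("pure-transport adjoint is the transpose: dot-product identity", {
  g <- tiny_grid()
  f <- tiny_forcing()
  # biology switched off: the forward map for P is linear
  p <- eco_parameters(Vm = 0, Gm = 0, Dp = 0, Dz = 0, e = 0)
  base <- uniform_state(g, N = 1, P = 0, Z = 1, D = 1)
  set.seed(53)
  x <- runif(g$npack)
  y <- runif(g$npack)
  sx <- base; sx$P <- x
  trx <- run_forward(g, f, p, sx, days = 1, open_boundary_rate = 0)
  Ax <- trx$final$P   # A x with A the 4-step linear transport operator
  tM <- Matrix::t(npzdvar:::build_transport_matrix(g, f, p$wp, 21600))
  Aty <- y
  for (k in 1:4) Aty <- as.numeric(tM %*% Aty)
  lhs <- sum(Ax * y)
  rhs <- sum(x * Aty)
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-12)
})

test_that("gradient projection and steepest descent behave as contracts say", {
  g <- coarse_grid()
  ips <- independent_points(g, spacing = 4, method = "spline")
  # uniform grid gradient of one: projected component n is the kappa column sum
  ones <- rep(1, nrow(ips$kappa))
  expect_equal(project_to_independent_points(ips, ones), colSums(ips$kappa),
               tolerance = 1e-12)
  # zero gradient leaves the control unchanged
  ctrl <- runif(nrow(ips$points))
  expect_identical(steepest_descent_step(ctrl, numeric(length(ctrl)), 0.5),
                   ctrl)
  # 1-D quadratic J = x^2/2, x0 = 1, unnormalized alpha = 0.5 -> x1 = 0.5
  expect_equal(steepest_descent_step(1, 1, 0.5, normalize = FALSE), 0.5)
})

test_that("assimilation recovers a plane on a small all-wet twin problem", {
  bath <- matrix(20, 10, 8)
  g <- bohai_grid(30, layer_thickness = c(5, 10), bathymetry = bath)
  f <- synthetic_forcing(g, days = 3, step_hours = 6, seed = 6,
                         current_amplitude = 0.05)
  p <- eco_parameters()
  LON <- matrix(g$lon, g$nx, g$ny); LAT <- matrix(g$lat, g$nx, g$ny, byrow = TRUE)
  plane <- 1 + 0.6 * (LON - min(g$lon)) + 0.4 * (LAT - min(g$lat))
  background <- spinup_state(g, f, p, P0 = surface_to_column(g, plane),
                             days = 1)
  init <- background; init$P <- surface_to_column(g, plane)
  obs <- observations_from_trajectory(run_forward(g, f, p, init, days = 3))
  ips <- independent_points(g, spacing = 4, method = "spline")
  ctrl0 <- rep(mean(plane[g$mask]), nrow(ips$points))
  # step0 per the 2-percent-of-range rule applied to the truth scale (the
  # uniform first guess has zero range of its own)
  res <- assimilate(g, f, p, obs, ips, ctrl0, background,
                    max_iterations = 60, ncf_threshold = 1e-8,
                    step0 = 0.02 * diff(range(plane[g$mask])))
  expect_equal(res$ncf_history[1], 1)
  expect_true(all(diff(res$ncf_history) <= 0))
  expect_lt(utils::tail(res$ncf_history, 1), 1e-3)
  expect_lt(rmse(res$final_field[g$mask], plane[g$mask]), 0.05)
  expect_length(res$ncf_history, res$iterations_run + 1)
})

test_that("assimilation is deterministic and detects an exact initial fit", {
  g <- tiny_grid()
  f <- tiny_forcing()
  p <- eco_parameters()
  background <- uniform_state(g, N = 6, P = 1, Z = 0.1, D = 0.1)
  ips <- independent_points(g, spacing = 2, method = "cressman")
  ctrl0 <- runif(nrow(ips$points), 0.5, 1.5)
  surf <- ips_expand(ips, ctrl0, as_matrix = TRUE, grid = g)
  init <- background; init$P <- surface_to_column(g, surf)
  obs <- observations_from_trajectory(run_forward(g, f, p, init, days = 2))
  r1 <- assimilate(g, f, p, obs, ips, ctrl0, background, max_iterations = 5)
  expect_equal(r1$ncf_history, 1)        # obs generated from the guess itself
  expect_equal(r1$iterations_run, 0L)
  # different guess: two runs, identical history
  ctrl2 <- ctrl0 + 0.3
  r2 <- assimilate(g, f, p, obs, ips, ctrl2, background, max_iterations = 8)
  r3 <- assimilate(g, f, p, obs, ips, ctrl2, background, max_iterations = 8)
  expect_identical(r2$ncf_history, r3$ncf_history)
  expect_identical(r2$final_control, r3$final_control)
})
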