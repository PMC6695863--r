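test_that("a zero-day run returns the initial state", {
  g <- tiny_grid()
  f <- tiny_forcing()
  s0 <- tiny_init()
  tr <- run_forward(g, f, eco_parameters(), s0, days = 0)
  expect_equal(tr$final, s0)
  expect_equal(ncol(tr$surface_P), 0)
})

test_that("total nitrogen is conserved over a closed-basin run", {
  g <- coarse_grid()
  f <- synthetic_forcing(g, days = 5, seed = 1)
  s0 <- uniform_state(g, N = 6, P = 1, Z = 0.1, D = 0.1)
  tr <- run_forward(g, f, eco_parameters(), s0, days = 5)
  expect_equal(total_nitrogen(g, tr$final), total_nitrogen(g, s0),
               tolerance = 1e-10)
  expect_equal(tr$clipped_n, 0)
})

test_that("a single-cell run matches a 0-D Euler oracle bitwise", {
  bath <- matrix(NA_real_, 5, 4)
  bath[3, 2] <- 4   # one wet cell, single 4 m layer
  g <- bohai_grid(60, layer_thickness = c(5, 10), bathymetry = bath)
  expect_equal(g$npack, 1L)
  f <- synthetic_forcing(g, days = 2, seed = 9, current_amplitude = 0)
  p <- eco_parameters()
  s0 <- list(N = 5, P = 1, Z = 0.2, D = 0.1)
  tr <- run_forward(g, f, p, s0, days = 2)
  # scalar ODE oracle with the same forward-Euler scheme and forcing samples
  x <- c(N = 5, P = 1, Z = 0.2, D = 0.1)
  atten <- exp(-p$Kext * g$layer_mid[1])
  for (it in 1:8) {
    T_c <- f$sst[3, 2, it]
    I <- f$irradiance[it] * atten
    tfa <- p$AQ10^((T_c - 10) / 10); tfb <- p$BQ10^((T_c - 10) / 10)
    U <- p$Vm * tfa * (x["N"] / (p$Ks + x["N"])) *
      ((I / p$Io) * exp(1 - I / p$Io)) * x["P"]
    G <- p$Gm * tfb * (1 - exp(-p$f_ivlev * x["P"])) * x["Z"]
    dx <- c(-U + p$theta * G + p$e * x["D"],
            U - G - p$Dp * x["P"],
            (p$gamma - p$theta) * G - p$Dz * x["Z"],
            (1 - p$gamma) * G + p$Dp * x["P"] + p$Dz * x["Z"] - p$e * x["D"])
    x <- x + 0.25 * dx
  }
  expect_identical(unname(tr$final$N), unname(x["N"]))
  expect_identical(unname(tr$final$P), unname(x["P"]))
  expect_identical(unname(tr$final$Z), unname(x["Z"]))
  expect_identical(unname(tr$final$D), unname(x["D"]))
})

test_that("forward run records surface P per step and validates coverage", {
  g <- tiny_grid()
  f <- tiny_forcing()
  tr <- run_forward(g, f, eco_parameters(), tiny_init(), days = 2)
  expect_equal(ncol(tr$surface_P), 8)   # 2 days at 6 h
  expect_equal(nrow(tr$surface_P), sum(g$mask))
  expect_true(all(is.finite(tr$surface_P)))
  expect_error(run_forward(g, f, eco_parameters(), tiny_init(), days = 3),
               "cover")
})

test_that("open-boundary relaxation pins edge cells toward the initial value", {
  g <- tiny_grid()  # edge cells are wet here
  expect_gt(length(npzdvar:::open_boundary_cells(g)), 0)
  f <- synthetic_forcing(g, days = 2, seed = 2, current_amplitude = 0,
                         kh = 0, kv = 0)
  p <- eco_parameters(Vm = 0, Gm = 0, Dp = 0, Dz = 0, e = 0, wp = 0, wd = 0)
  s0 <- uniform_state(g, N = 6, P = 1, Z = 0.1, D = 0.1)
  ob <- npzdvar:::open_boundary_cells(g)[1]
  s0$P[ob] <- 5
  tr <- run_forward(g, f, p, s0, days = 2, open_boundary_rate = 0.5)
  # no transport, no biology: relaxation toward the initial value is inert
  # when the state still equals it
  expect_equal(tr$final$P[ob], 5)
})

test_that("spin-up produces positive Z and D from the model itself", {
  g <- tiny_grid()
  f <- tiny_forcing()
  st <- spinup_state(g, f, eco_parameters(), P0 = rep(1, g$npack), days = 2)
  expect_true(all(st$Z > 0) && all(st$D > 0))
  expect_false(all(st$Z == 0.1))  # actually evolved
  expect_true(all(st$N == 6))
})
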