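#' Observations and the quadratic cost function
#'
#' Observations are surface-layer phytoplankton values on the wet surface
#' cells at model steps, with a 0/1 weighting matrix `W` marking where an
#' observation exists. The cost is the discrete weighted sum of squares
#' `J = 1/2 sum_t sum_cells W (P - P_o)^2` over the time and space domain.
#'
#' @param values matrix (wet surface cells x observation times), mmol N m^-3
#' @param weights 0/1 matrix of the same shape; default all 1
#' @param times integer model-step indices the columns refer to (default
#'   `1:ncol(values)`)
#' @return object of class `npzd_obs`
#' @export
observation_set <- function(values, weights = NULL, times = seq_len(ncol(values))) {
  values <- as.matrix(values)
  if (is.null(weights)) weights <- matrix(1, nrow(values), ncol(values))
  weights <- as.matrix(weights)
  stopifnot(all(dim(weights) == dim(values)), length(times) == ncol(values))
  if (!all(weights %in% c(0, 1))) stop("weights must be 0 or 1")
  if (any(!is.finite(values[weights == 1]))) {
    stop("observed values must be finite where W = 1")
  }
  structure(list(values = values, weights = weights, times = as.integer(times)),
            class = "npzd_obs")
}

#' Pseudo-observations from a model trajectory
#'
#' Twin-experiment helper: every recorded surface phytoplankton value of the
#' trajectory becomes an observation with weight 1.
#' @param trajectory an `npzd_trajectory`
#' @return an `npzd_obs`
#' @export
observations_from_trajectory <- function(trajectory) {
  observation_set(trajectory$surface_P)
}

#' @rdname observation_set
#' @param trajectory an `npzd_trajectory` (or a surface-P matrix)
#' @param obs an `npzd_obs`
#' @return `cost_function`: scalar J, (mmol N m^-3)^2-weighted
#' @export
cost_function <- function(trajectory, obs) {
  P <- if (inherits(trajectory, "npzd_trajectory")) trajectory$surface_P
       else as.matrix(trajectory)
  stopifnot(inherits(obs, "npzd_obs"))
  if (nrow(P) != nrow(obs$values) || ncol(P) < max(obs$times)) {
    stop("trajectory and observations do not match")
  }
  Pm <- P[, obs$times, drop = FALSE]
  0.5 * sum(obs$weights * (Pm - obs$values)^2)
}

#' Adjoint sweep: gradient of the cost with respect to the initial state
#'
#' Backward integration of the exact discrete adjoint of the operator-split
#' forward step (transpose of the sparse transport operators, transpose of
#' the linearized Euler biology including the positivity-clipping branches),
#' with the misfit `W (P - P_o)` injected at each observation time. Returns
#' the gradient of J with respect to the full initial phytoplankton field
#' (and the other compartments, rarely needed).
#'
#' @param trajectory an `npzd_trajectory` produced with `store = TRUE`
#' @param obs an `npzd_obs`
#' @param grid,forcing,params the setup of the forward run
#' @param tops prebuilt transposed transport operators (optimization for
#'   iterative callers)
#' @return list: `P` (packed gradient dJ/dP(t=0)), `N`, `Z`, `D` likewise
#' @export
adjoint_sweep <- function(trajectory, obs, grid, forcing, params,
                          tops = NULL) {
  stopifnot(inherits(trajectory, "npzd_trajectory"))
  if (is.null(trajectory$stored)) {
    stop("adjoint needs a trajectory run with store = TRUE")
  }
  nsteps <- trajectory$nsteps
  if (max(obs$times) > nsteps) stop("observation times exceed the trajectory")
  dt_sec <- trajectory$step_hours * 3600
  dt_bio <- (trajectory$step_hours / 24) / trajectory$bio_substeps
  if (is.null(tops)) {
    ops <- transport_operators(grid, forcing, params, dt_sec)
    tops <- list(M0 = Matrix::t(ops$M0), Mp = Matrix::t(ops$Mp),
                 Md = Matrix::t(ops$Md))
  }
  tM0 <- tops$M0; tMp <- tops$Mp; tMd <- tops$Md
  aux <- step_aux(grid, params)
  ob <- open_boundary_cells(grid)
  r <- trajectory$open_boundary_rate

  n <- grid$npack
  lam <- list(N = numeric(n), P = numeric(n), Z = numeric(n), D = numeric(n))
  lam_ref <- if (length(ob)) lapply(lam, function(v) v[ob] * 0) else NULL
  misfit <- matrix(0, nrow(trajectory$surface_P), nsteps)
  Pm <- trajectory$surface_P[, obs$times, drop = FALSE]
  misfit[, obs$times] <- obs$weights * (Pm - obs$values)

  for (it in rev(seq_len(nsteps))) {
    lam$P[grid$surface_pack] <- lam$P[grid$surface_pack] + misfit[, it]
    # reverse the biology sub-cycle: recompute the substep chain forward,
    # then backpropagate through it in reverse
    st0 <- trajectory$stored[[it]]
    Tc <- forcing$sst[, , it][aux$ij]
    Iz <- forcing$irradiance[it] * aux$atten
    nsub <- trajectory$bio_substeps
    chain <- vector("list", nsub)
    s <- st0
    for (sb in seq_len(nsub)) {
      chain[[sb]] <- s
      if (sb < nsub) s <- bio_step(s, Tc, Iz, params, dt_bio,
                                   aux$surface)[c("N", "P", "Z", "D")]
    }
    for (sb in rev(seq_len(nsub))) {
      lam <- bio_step_adjoint(lam, chain[[sb]], Tc, Iz, params, dt_bio,
                              aux$surface)
    }
    if (length(ob)) {  # reverse the open-boundary relaxation
      for (nm in names(lam)) {
        lam_ref[[nm]] <- lam_ref[[nm]] + r * lam[[nm]][ob]
        lam[[nm]][ob] <- (1 - r) * lam[[nm]][ob]
      }
    }
    lam <- list(N = as.numeric(tM0 %*% lam$N),
                P = as.numeric(tMp %*% lam$P),
                Z = as.numeric(tM0 %*% lam$Z),
                D = as.numeric(tMd %*% lam$D))
  }
  if (length(ob)) {  # relaxation reference is the initial tracer value
    for (nm in names(lam)) lam[[nm]][ob] <- lam[[nm]][ob] + lam_ref[[nm]]
  }
  lam
}

#' Collapse a 3-D initial-phytoplankton gradient to the surface control space
#'
#' The control is a surface field expanded down the column by the standard
#' vertical profile; its gradient is the profile-weighted vertical sum of the
#' 3-D gradient.
#' @param grid an `npzd_grid`
#' @param grad_packed packed gradient over active cells
#' @return gradient over wet surface cells (vector)
#' @export
collapse_column_gradient <- function(grid, grad_packed) {
  aux_k <- ((grid$pidx - 1L) %/% (grid$nx * grid$ny)) + 1L
  ij <- ((grid$pidx - 1L) %% (grid$nx * grid$ny)) + 1L
  w <- vertical_profile(grid)[aux_k]
  g <- matrix(0, grid$nx, grid$ny)
  acc <- rowsum(grad_packed * w, group = ij)
  g[as.integer(rownames(acc))] <- acc[, 1]
  g[grid$mask]
}

#' One steepest-descent control update
#'
#' Moves the control along the negative gradient, normalized by its
#' max-norm: `control - alpha * g / max|g|`. With `normalize = FALSE` the raw
#' gradient is used (the textbook update).
#'
#' @param control numeric vector
#' @param gradient same length
#' @param alpha step size (in control units when normalized)
#' @param normalize divide the gradient by its max-norm (default TRUE)
#' @return updated control vector
#' @export
steepest_descent_step <- function(control, gradient, alpha, normalize = TRUE) {
  stopifnot(length(control) == length(gradient))
  gmax <- max(abs(gradient))
  if (gmax == 0) return(control)
  d <- if (normalize) gradient / gmax else gradient
  control - alpha * d
}

#' Variational assimilation of surface phytoplankton observations
#'
#' The full loop: expand the independent-point control to the initial surface
#' phytoplankton field (and down the column), run the forward model, measure
#' the cost against the observations, run the adjoint for the gradient,
#' project it onto the independent points, and update by steepest descent.
#' The step size starts at `step0` (default 2 percent of the initial control
#' range) and halves whenever a trial increases the cost (it stays halved);
#' an iteration that cannot find a decrease within `max_halvings` halvings
#' ends the loop. Setting `step_growth` above 1 re-grows the step after each
#' accepted iteration (faster, but it erodes the interpolator ordering that
#' plain fixed-step descent exhibits). Iteration also stops at
#' `max_iterations` or when the normalized cost `J_k / J_0` drops below
#' `ncf_threshold`.
#'
#' @param grid,forcing,params model setup
#' @param obs an `npzd_obs` (the assimilation window is
#'   `max(obs$times)` steps)
#' @param ips an `npzd_ips` defining control reduction and expansion
#' @param control0 initial control (one value per independent point)
#' @param background initial-state template: list with `N`, `Z`, `D` packed
#'   vectors (e.g. from [spinup_state()]); the P component is replaced by the
#'   expanded control
#' @param max_iterations iteration cap (default 100)
#' @param ncf_threshold stop when `J/J0` falls below this (default 5e-4)
#' @param step0 initial step size in control units (default
#'   `0.02 * diff(range(control0))`, or 0.02 if the range is degenerate)
#' @param step_growth growth factor after an accepted step (default 1.0,
#'   the fixed-step-with-halving policy)
#' @param max_halvings halvings tried within one iteration (default 8)
#' @param bio_substeps passed to [run_forward()]
#' @param verbose print one line per iteration
#' @return object of class `npzd_assim`: `ncf_history` (starts at 1, one
#'   entry per accepted iteration plus the initial value), `j_history`,
#'   `final_control`, `final_field` (recovered initial surface P, `nx x ny`),
#'   `iterations_run`, `converged` reason
#' @export
assimilate <- function(grid, forcing, params, obs, ips, control0, background,
                       max_iterations = 100, ncf_threshold = 5e-4,
                       step0 = NULL, step_growth = 1.0, max_halvings = 8,
                       bio_substeps = 1L, verbose = FALSE) {
  stopifnot(inherits(obs, "npzd_obs"), inherits(ips, "npzd_ips"))
  days <- max(obs$times) * forcing$step_hours / 24
  if (is.null(step0)) {
    # 2 percent of the control range; a uniform first guess has zero range,
    # so fall back to 2 percent of a unit concentration (1 mmol N m-3)
    rng <- diff(range(control0))
    step0 <- 0.02 * if (rng > 0) rng else 1
  }
  ops <- transport_operators(grid, forcing, params, forcing$step_hours * 3600)
  tops <- list(M0 = Matrix::t(ops$M0), Mp = Matrix::t(ops$Mp),
               Md = Matrix::t(ops$Md))
  run_control <- function(ctrl, store = FALSE) {
    surf <- ips_expand(ips, ctrl, as_matrix = TRUE, grid = grid)
    init <- background
    init$P <- surface_to_column(grid, surf)
    run_forward(grid, forcing, params, init, days = days, store = store,
                bio_substeps = bio_substeps, ops = ops)
  }
  control <- control0
  traj <- run_control(control, store = TRUE)
  J <- cost_function(traj, obs)
  J0 <- J
  j_hist <- J
  alpha <- step0
  iterations <- 0L
  converged <- "max_iterations"
  if (J0 == 0) {
    converged <- "initial fit exact"
  } else {
    for (iter in seq_len(max_iterations)) {
      if (J / J0 < ncf_threshold) { converged <- "ncf_threshold"; break }
      g3 <- adjoint_sweep(traj, obs, grid, forcing, params, tops = tops)
      gsurf <- collapse_column_gradient(grid, g3$P)
      gctrl <- project_to_independent_points(ips, gsurf)
      if (max(abs(gctrl)) == 0) { converged <- "zero gradient"; break }
      accepted <- FALSE
      for (h in seq_len(max_halvings + 1L)) {
        trial <- steepest_descent_step(control, gctrl, alpha)
        ttraj <- run_control(trial, store = TRUE)
        Jt <- cost_function(ttraj, obs)
        if (Jt < J) {
          control <- trial; traj <- ttraj; J <- Jt
          alpha <- alpha * step_growth
          accepted <- TRUE
          break
        }
        alpha <- alpha / 2
      }
      if (!accepted) { converged <- "no descent"; break }
      iterations <- iter
      j_hist <- c(j_hist, J)
      if (verbose) {
        message(sprintf("iter %3d  J %.6e  NCF %.3e  step %.3e",
                        iter, J, J / J0, alpha))
      }
    }
  }
  final_surf <- ips_expand(ips, control, as_matrix = TRUE, grid = grid)
  ncf_hist <- if (J0 > 0) j_hist / J0 else rep(1, length(j_hist))
  structure(list(
    ncf_history = ncf_hist, j_history = j_hist,
    final_control = control, final_field = final_surf,
    iterations_run = iterations, converged = converged,
    ips_method = ips$method), class = "npzd_assim")
}

#' @export
print.npzd_assim <- function(x, ...) {
  cat(sprintf("<npzd_assim %s> %d iterations, final NCF %.3e (%s)\n",
              x$ips_method, x$iterations_run, utils::tail(x$ncf_history, 1),
              x$converged))
  invisible(x)
}
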