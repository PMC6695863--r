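#' Run an idealized twin experiment
#'
#' The full pipeline of a twin experiment: prescribe a truth phytoplankton
#' field (`IE1` paraboloid or `IE2` temperature-driven), run the forward
#' model from it to generate pseudo-observations of surface P at every step,
#' then assimilate those observations starting from a uniform initial guess
#' (the domain mean of the truth surface) with the control reduced to
#' independent points and expanded by the chosen interpolator. Skill is
#' measured between the recovered initial surface field and the truth over
#' wet cells.
#'
#' @param cfg an `npzd_config` (see [load_config()]); `NULL` for defaults
#' @param truth_kind `"IE1"` or `"IE2"` (default: the config's)
#' @param method `"spline"` or `"cressman"` (default: the config's)
#' @param setup optional precomputed list from [twin_setup()] to share the
#'   grid, forcing, truth runs and spin-up between experiments
#' @param verbose print per-iteration assimilation lines
#' @return list: `result` (an `npzd_assim`), `metrics` (a `metric_bundle`
#'   of the recovered vs truth surface), `truth`, `setup`
#' @examples
#' \donttest{
#' cfg <- load_config(NULL)
#' cfg$domain$resolution_arcmin <- 20   # coarse demo
#' cfg$forcing$days <- 5
#' tw <- run_twin_experiment(cfg, "IE1", "spline")
#' tw$metrics
#' }
#' @export
run_twin_experiment <- function(cfg = NULL, truth_kind = NULL, method = NULL,
                                setup = NULL, verbose = FALSE) {
  if (is.null(cfg)) cfg <- load_config(NULL)
  if (!is.null(truth_kind)) cfg$experiment$kind <- truth_kind
  if (!is.null(method)) cfg$ips$method <- method
  if (is.null(setup)) setup <- twin_setup(cfg)
  s <- setup
  radius <- if (is.null(cfg$ips$radius)) 2.5 * cfg$ips$spacing else cfg$ips$radius
  ips <- independent_points(s$grid, spacing = cfg$ips$spacing,
                            method = cfg$ips$method, radius = radius)
  guess <- mean(s$truth$surface[s$grid$mask])
  control0 <- rep(guess, nrow(ips$points))
  res <- assimilate(
    s$grid, s$forcing, s$params, s$obs, ips, control0, s$background,
    max_iterations = cfg$assimilation$max_iterations,
    ncf_threshold = cfg$assimilation$ncf_threshold,
    step0 = cfg$assimilation$step0,
    step_growth = cfg$assimilation$step_growth,
    max_halvings = cfg$assimilation$max_halvings,
    bio_substeps = cfg$model$bio_substeps, verbose = verbose)
  mb <- metric_bundle(res$final_field[s$grid$mask],
                      s$truth$surface[s$grid$mask],
                      j_history = res$j_history)
  list(result = res, metrics = mb, truth = s$truth, setup = s, ips = ips)
}

#' Shared twin-experiment setup
#'
#' Builds the grid, forcing, truth field, spun-up background state and the
#' pseudo-observations for a configuration. Separated out so the spline and
#' Cressman runs of a comparison reuse the same world.
#' @param cfg an `npzd_config`
#' @return list: `grid`, `forcing`, `params`, `truth`, `background`, `obs`
#' @export
twin_setup <- function(cfg) {
  grid <- bohai_grid(resolution_arcmin = cfg$domain$resolution_arcmin,
                     layer_thickness = cfg$domain$layer_thickness)
  forcing <- synthetic_forcing(
    grid, days = cfg$forcing$days, step_hours = cfg$forcing$step_hours,
    seed = cfg$seed, current_amplitude = cfg$forcing$current_amplitude,
    kh = cfg$forcing$kh, kv = cfg$forcing$kv,
    sst_mean = cfg$forcing$sst_mean,
    irradiance_max = cfg$forcing$irradiance_max)
  params <- config_params(cfg)
  truth <- switch(cfg$experiment$kind,
    IE1 = truth_ie1(grid, peak = cfg$experiment$peak,
                    floor = cfg$experiment$floor),
    IE2 = truth_ie2(grid, forcing, p_ref = cfg$experiment$p_ref,
                    slope = cfg$experiment$slope))
  background <- spinup_state(grid, forcing, params, P0 = truth$field,
                             N0 = cfg$model$n_initial,
                             days = min(cfg$model$spinup_days, forcing$days))
  init_truth <- background
  init_truth$P <- truth$field
  truth_traj <- run_forward(grid, forcing, params, init_truth,
                            bio_substeps = cfg$model$bio_substeps)
  obs <- observations_from_trajectory(truth_traj)
  list(grid = grid, forcing = forcing, params = params, truth = truth,
       background = background, obs = obs)
}
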