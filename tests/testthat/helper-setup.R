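# Shared fixtures, built lazily and cached for the whole test run.
.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .cache)) {
    assign(name, force(expr), envir = .cache)
  }
  get(name, envir = .cache)
}

# Coarse idealized grid (15 x 12 columns) for fast structural tests.
coarse_grid <- function() cached("coarse_grid", bohai_grid(resolution_arcmin = 20))

# Tiny rectangular basin built from a user bathymetry: 5 x 4 columns,
# two layers, one dry corner, one shallow cell; edge cells are wet so the
# open-boundary path is exercised.
tiny_grid <- function() cached("tiny_grid", {
  bath <- matrix(12, 5, 4)
  bath[1, 1] <- NA
  bath[5, 4] <- 8
  bohai_grid(resolution_arcmin = 60, layer_thickness = c(5, 10),
             bathymetry = bath)
})

tiny_forcing <- function() cached("tiny_forcing", {
  synthetic_forcing(tiny_grid(), days = 2, step_hours = 6, seed = 3,
                    current_amplitude = 0.05)
})

# Random positive initial state away from the clipping kinks.
tiny_init <- function(seed = 4) {
  g <- tiny_grid()
  set.seed(seed)
  list(N = runif(g$npack, 4, 8), P = runif(g$npack, 0.5, 2),
       Z = runif(g$npack, 0.05, 0.2), D = runif(g$npack, 0.05, 0.2))
}

# Default full-resolution twin-experiment world, shared by the acceptance
# criteria (expensive: built once).
default_setup <- function(kind) {
  cached(paste0("setup_", kind), {
    cfg <- load_config(NULL)
    cfg$experiment$kind <- kind
    twin_setup(cfg)
  })
}

ie1_spline <- function() cached("ie1_spline", {
  run_twin_experiment(load_config(NULL), "IE1", "spline",
                      setup = default_setup("IE1"))
})

ie1_cressman <- function() cached("ie1_cressman", {
  run_twin_experiment(load_config(NULL), "IE1", "cressman",
                      setup = default_setup("IE1"))
})

ie2_spline <- function() cached("ie2_spline", {
  run_twin_experiment(load_config(NULL), "IE2", "spline",
                      setup = default_setup("IE2"))
})
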