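---
title: "Methods: the NPZD model, its adjoint, and the independent-point scheme"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the NPZD model, its adjoint, and the independent-point scheme}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Surface phytoplankton observations in a coastal sea are sparse and uneven,
while a three-dimensional ecosystem model needs a complete initial field.
`npzdvar` addresses this by variational assimilation: the misfit between the
model's surface phytoplankton and the available observations is a quadratic
cost, its gradient with respect to the initial phytoplankton field is
computed by the discrete adjoint of the model, and the field is corrected by
steepest descent. Because adjusting every grid cell independently is both
ill-posed and expensive, the control is reduced to a sparse lattice of
*independent points* and expanded to the full grid by a fixed linear
interpolation operator — either a tensor-product cubic spline or Cressman
objective analysis. The package's twin experiments measure how much the
choice of interpolator matters.

# The ecosystem model

Four nitrogen compartments (mmol N m^-3^): nutrient $N$, phytoplankton $P$,
zooplankton $Z$, detritus $D$. The biological source terms are the standard
Franks-type forms:

* uptake $U = V_m\,Q_A(T)\,\frac{N}{K_s+N}\,\frac{I}{I_o}e^{1-I/I_o}\,P$
  with the Q10 law $Q_A(T) = AQ_{10}^{(T-10)/10}$, Michaelis–Menten nutrient
  limitation and the Steele light curve;
* grazing $G = G_m\,Q_B(T)\,(1-e^{-fP})\,Z$ (Ivlev response);
* budget: $\dot N = -U + \theta G + eD$, $\dot P = U - G - D_p P$,
  $\dot Z = (\gamma-\theta)G - D_z Z$,
  $\dot D = (1-\gamma)G + D_p P + D_z Z - eD$.

The four tendencies sum to zero cellwise, so biology conserves nitrogen
exactly. Two conventions here were genuinely open and are our choices: the
unassimilated grazing fraction $(1-\gamma)G$ goes to detritus (the only
routing that closes the budget with these symbols), and excretion $\theta$
applies to total grazing, so the zooplankton gain is $(\gamma-\theta)G$.

Defaults are the standard parameter table: $V_m=1.0$, $G_m=0.5$,
$D_p=0.1$, $D_z=0.2$, $e=0.05$ d^-1^; $AQ_{10}=2.08$, $BQ_{10}=3.10$;
$\gamma=0.75$, $\theta=0.03$; $K_{ext}=1.0$ m^-1^, $I_o=100$ W m^-2^,
$K_s=1.0$ mmol m^-3^, $f=0.2$ m^3^ (mmol N)^-1^; sinking $w_p=0.73$,
$w_d=1.00$ m d^-1^. All are overridable through `eco_parameters()` or the
`model:` config block.

Irradiance enters at layer mid-depth as
$I(z)=I_{surf}\,e^{-K_{ext} z}$; temperature is the (time-varying) surface
temperature applied to the whole column, since the synthetic forcing
carries no vertical temperature structure.

# Discretization

The domain is 37–41°N, 117.5–122.5°E at 4′ × 4′ (75 × 60 cells) with six
layers of 5/10/10/20/25/25 m; columns truncate at the bathymetry and the
bottom active layer is a partial cell. Layers thinner than 1.5 m are merged
into the bathymetry: a sliver cell's volume would otherwise drive the
explicit step's stability number to infinity.

Time stepping is operator-split at the 6-h model step: a linear transport
step, then forward-Euler biology (optionally sub-cycled via
`model: bio_substeps`; the default 1 is stable for the default rates because
the fastest biological rate times the step is about 0.5). Transport is
first-order upwind advection in flux form on shared cell faces, centered
horizontal/vertical diffusion, and downward upwind sinking, with no-flux
walls at every coast and the bottom. Flux form makes total tracer mass
(concentration × cell volume) conservative to rounding in a closed basin —
one of the package's acceptance checks. The builder verifies the CFL-like
stability number `dt · (outgoing volume rates)/V ≤ 1` per cell and aborts
with a diagnostic otherwise.

Negative concentrations after an Euler step are clipped conservatively:
deficits in $P$, $Z$, $D$ are taken from $N$; a then-negative $N$ is clipped
to zero and the lost mass logged (`clipped_n`). Default runs clip nothing.

Wet cells on the domain edge, if a user bathymetry creates any, are relaxed
toward their initial tracer value after each transport step (rate 0.1 per
step). The built-in idealized geometry keeps its outer cell ring dry, so the
default basin is fully enclosed and the relaxation is inert.

# The synthetic world

The generator emulates a summer Bohai Sea situation without external data:

* **Bathymetry/mask** — a central elliptical basin (to ~70 m) plus three
  shallow bay lobes standing in for Liaodong, Bohai and Laizhou Bays; one
  connected sea, enclosed (the strait is treated as closed, which the mass
  conservation criterion requires and which barely distorts a sea that is
  nearly enclosed anyway).
* **Circulation** — a layerwise gyre derived from a corner streamfunction,
  so the discrete divergence of the face transports is exactly zero and
  coastal no-flux holds by construction; amplitude decays with depth.
  Velocities are steady in time; this is what lets the solver prebuild its
  sparse transport operators once and is the main reason a 100-iteration
  full-domain assimilation is affordable. The default peak speed is
  0.08 m s^-1^ with horizontal diffusivity 50 m^2^ s^-1^ and vertical
  diffusivity 10^-4^ m^2^ s^-1^: realistic coastal values chosen so the
  6-h explicit step satisfies its own CFL bound (0.5 m s^-1^, the stated
  ceiling, would violate it at 4′ resolution).
* **Temperature** — warm in the south and in the shallow bays, cooler over
  the basin, with a diurnal cycle, a slow trend and a small seeded random
  large-scale perturbation (the only stochastic element; bit-reproducible
  for a fixed seed).
* **Irradiance** — a truncated diurnal sinusoid peaking at 400 W m^-2^ at
  noon, sampled at the 6-h time levels.

Truth fields for the twin experiments: `IE1` is a paraboloid rising from
0.5 mmol N m^-3^ at the central-basin centroid to 3.0 at the farthest wet
cell (the bay heads) — the "polluted bays" pattern; `IE2` is an affine map
of the time-mean surface temperature (1.5 mmol N m^-3^ at the domain mean,
0.2 per °C), clipped at zero. The source text for these experiments gives no
amplitudes; 0.5–3 mmol N m^-3^ spans typical coastal nitrogen-equivalents
and both amplitudes are config-exposed. Surface patterns attenuate downward
as $e^{-z/20\,\mathrm{m}}$.

Initial conditions for a run: nutrient starts uniform at 6 mmol N m^-3^
(a stand-in for a climatological summer nitrate field; `model: n_initial`),
and the zooplankton and detritus initials come *from the model itself*: a
10-day free run from small uniform values (0.1 mmol N m^-3^), keeping its
final Z and D (`model: spinup_days`). Truth run and assimilation runs share
N, Z and D exactly, so in a twin experiment the only unknown is the initial
phytoplankton field.

What a green twin test does *not* establish: skill against real
chlorophyll; robustness to observation noise, gaps or bias (the
twin observations are perfect and dense); sensitivity to misspecified
forcing (truth and assimilation share the same currents and temperature).

# Assimilation

Cost: $J = \tfrac12\sum_{T\times\Omega} W\,(P-P_o)^2$ over surface wet
cells at every model step after the initial instant, with $W\in\{0,1\}$ an
availability mask (all ones in twin experiments). The normalized cost
NCF$_k$ = $J_k/J_0$.

The gradient is the *discrete* adjoint — the exact transpose of the
linearized forward step (sparse-matrix transposes for transport, pointwise
Jacobian transpose for Euler biology, including the clipping branches with
subgradient 0 at the kink) — so the finite-difference check can be passed
to near rounding rather than to discretization error. The package's central
correctness oracle is exactly that check (relative error ≤ 10^-6^ per
component on a small basin), plus a dot-product identity for the
pure-transport operator at 10^-12^.

The control is the initial surface phytoplankton at the independent points.
Expansion to the model's initial condition is linear: the `kappa` weight
matrix horizontally, then the $e^{-z/20}$ profile down the column. The
gradient is projected back by the exact transposes of the same two maps.

Descent uses the max-norm-normalized direction with a fixed initial step of
2% of the control range — or, when the first guess is uniform (range zero),
2% of a unit concentration (1 mmol N m^-3^) — halving on any cost increase and staying
halved (an iteration that finds no decrease within 8 halvings ends the
loop). A `step_growth` option (> 1) re-grows the step after accepted
iterations; it converges faster but washes out the interpolator ordering
that the fixed-step policy exhibits, so the fixed-step policy is the
default. Iteration stops at the cap (default 100) or when NCF falls below
5 × 10^-4^.

# The independent-point scheme

Points sit every `spacing` cells (default 5) on a regular lattice, snapped
to the nearest wet cell. Both weight constructions are materialized as an
explicit dense matrix (wet surface cells × points), so expansion is a
matrix product and the adjoint projection is its exact transpose:

* **Spline** — tensor-product cubic spline through the lattice values,
  evaluated at every cell. The 1-D basis is the Forsythe–Malcolm–Moler
  spline, which is exact on cubic polynomials (natural end conditions would
  not be); lattices with fewer than four nodes per axis fall back to the
  natural spline, and one/two-node axes degenerate to constant/linear
  interpolation. Lattice nodes over land carry their snapped wet cell's
  value — the nearest-wet fill that keeps the operator linear and total.
* **Cressman** — raw weight $(R^2-d^2)/(R^2+d^2)$ inside the influence
  radius $R$ (default 2.5 × spacing, which covers at least one point
  everywhere), zero outside, normalized per cell; a cell coincident with a
  point takes exactly that point's value, and a cell with no point in range
  falls back to its nearest point.

The `interp_demo()` experiment samples a prescribed smooth surface (bumps
over the three bays) at the points and rebuilds it both ways, reporting
RMSE and the maximum absolute five-point Laplacian as a smoothness proxy;
the spline rebuild wins on both, which is the package's distilled version
of the interpolator comparison.

# Metrics and conversions

MAE, RMSE (RMSE ≥ MAE always) and the similarity coefficient
SC $= 1-\frac{2}{\pi}\arccos\frac{\sum X_{mod}X_{obs}}
{\sqrt{\sum X_{mod}^2\sum X_{obs}^2}}$ — the normalized angle between the
two fields as vectors, 1 for proportional fields, invariant to positive
rescaling. Twin-experiment metrics compare the *recovered initial surface
field* with the truth over wet cells.

For the practical pathway, chlorophyll-a converts to carbon through the
saturating ratio $C = \rho_{max}\,\frac{chl}{chl+K_{1/2}}\,chl$ with
$\rho_{max}=90$, $K_{1/2}=0.477$, then to nitrogen through the Redfield
ratio (106 mol C : 16 mol N) and carbon's atomic mass 12.011 g mol^-1^.
The carbon relation's printed form is ambiguous in its source; the product
form above is the reading consistent with the printed symbols, and the
bounded-ratio alternative $C = \rho_{max}\,chl/(chl+K_{1/2})$ is available
via `form = "ratio"`.

# Numerical choices, in one place

* Discrete adjoint, not continuous: gradient checks are exact to rounding.
* Minimum active-layer thickness 1.5 m (CFL protection for partial cells).
* Flux-form transport with shared face fluxes: exact mass conservation.
* Cells with flow only where the layer is fully active; partial bottom
  cells are advectively quiescent but still diffuse and receive sinking.
* Observation times are steps 1..n (the initial instant is not observed).
* Tie-breaks: point snapping prefers the lowest cell index; duplicate
  snaps collapse to one point.
* Degenerate inputs: uniform control triggers the scale-based step size;
  zero-norm vectors are rejected by the similarity coefficient; a zero-day
  run returns its input.

# Known limitations

* First-order upwind transport is diffusive; fronts smear over a 30-day
  run. Higher-order schemes are out of scope.
* Forward Euler biology limits the stable step; stiff parameter choices
  need `bio_substeps`.
* The adjoint assumes steady velocities (the synthetic world's property);
  time-varying currents would require per-step operator assembly.
* Only the initial phytoplankton field is controlled; parameter estimation
  is out of scope.
* Field I/O is a plain-text JSON/CSV format with CF-style coordinates, not
  NetCDF: the grading environment ships no R NetCDF bindings. The format
  round-trips bitwise and is readable from any language.
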