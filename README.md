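# npzdvar

Variational assimilation of surface phytoplankton into a nitrogen-based
NPZD (nutrient–phytoplankton–zooplankton–detritus) ecosystem model, with
the control field reduced to *independent points* and expanded to the full
grid by either tensor-product cubic **spline interpolation (SI)** or
**Cressman interpolation (CI)**. The package ships a synthetic Bohai Sea
configuration (idealized bathymetry, gyre circulation, summer temperature
and irradiance), so its idealized twin experiments — which measure how much
the choice of interpolator matters — run end to end with no external data.

Audience: coastal/biogeochemical modellers and data-assimilation
practitioners who want a small, fully testable 4D-Var-style workbench.

## The model and method in brief

Compartments N, P, Z, D (mmol N m⁻³) evolve under operator-split transport
(flux-form upwind advection + diffusion + sinking on a 75 × 60 × 6 masked
grid, 4′ × 4′, layers 5/10/10/20/25/25 m) and Franks-type biology:
Michaelis–Menten nutrient limitation, Steele light curve, Q10 temperature
laws and Ivlev grazing, closed so the four tendencies sum to zero.

Assimilation minimizes

J(P) = ½ Σ_{T×Ω} W (P − P_o)²

over the initial surface phytoplankton field by steepest descent, with the
gradient from the **exact discrete adjoint** of the model (verified against
central finite differences to ≤ 10⁻⁶ relative per component). The control
lives on a sparse point lattice and is expanded by a fixed linear operator
κ (Eq. p_ij = Σ_n κ_ijn p_n), built either from a cubic spline or from
Cressman weights (R² − d²)/(R² + d²); the gradient is projected back by the
exact transpose κᵀ. Skill metrics: normalized cost function (NCF = J_k/J₀),
MAE, RMSE and the similarity coefficient
SC = 1 − (2/π)·arccos(⟨X_mod, X_obs⟩ / (‖X_mod‖‖X_obs‖)).

## Worked example

A complete twin experiment at reduced resolution (20′ grid, ~15 s per
method; drop the two overrides for the full 4′ configuration):

```r
library(npzdvar)
cfg <- load_config(NULL)                  # the default synthetic world
cfg$domain$resolution_arcmin <- 20        # coarse demo
cfg$ips$spacing <- 3
si <- run_twin_experiment(cfg, "IE1", "spline")
ci <- run_twin_experiment(cfg, "IE1", "cressman", setup = si$setup)
print(si$metrics)
print(ci$metrics)
```

```
<metric_bundle> NCF 1.917e-02  MAE 0.0712  RMSE 0.1412  SC 0.940  (m = 90)
<metric_bundle> NCF 3.097e-01  MAE 0.3093  RMSE 0.3867  SC 0.844  (m = 90)
```

Reading: the truth is a paraboloid (high P in the three bays, low over the
central basin). Its forward run provides dense pseudo-observations of
surface P; assimilation starts from a uniform guess. After 100 steepest-
descent iterations the spline-based scheme has cut the cost by a factor of
~50 and recovers the truth surface with similarity coefficient 0.94, while
the Cressman-based scheme lags on every metric (NCF 0.31, SC 0.84) — the
package's distilled version of the interpolator comparison. The full
default 4′ configuration shows the same ordering (see the acceptance
criteria in `tests/testthat/test-acceptance.R`).

The interpolators can also be compared directly, without the model:

```r
demo <- interp_demo(bohai_grid(), spacing = 5)
demo$stats
#     method       rmse max_curvature
# 1   spline 0.01631941    0.05711803
# 2 cressman 0.17535838    2.04179197
```

## Command line

```sh
Rscript inst/scripts/npzd twin        --config cfg.yaml --seed 1 --output out/
Rscript inst/scripts/npzd interp-demo --output out/
Rscript inst/scripts/npzd metrics --fields model.json,obs.json --output out/
```

Each run writes its outputs (JSON fields with CF-style coordinates, CSV
NCF history, JSON metrics) plus a provenance record (config hash, seed,
package version).

## Further reading

`vignettes/npzdvar-methods.Rmd` documents the governing equations, the
synthetic world and its limits, all numerical choices (CFL handling,
clipping, step-size policy, spline end conditions) and what a green twin
test does and does not establish.
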