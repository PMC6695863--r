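Package: npzdvar
Title: NPZD Ecosystem Model with Adjoint Assimilation and Independent-Point Interpolation
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A nitrogen-based nutrient-phytoplankton-zooplankton-detritus (NPZD)
    ecosystem model on a structured coastal grid, with a discrete adjoint,
    variational (4D-Var style) assimilation of surface phytoplankton
    observations, and an independent-point scheme in which the control field is
    reduced to a sparse lattice of points and expanded to the full grid by
    either tensor-product cubic spline interpolation or Cressman objective
    analysis. Ships a synthetic Bohai Sea configuration (idealized bathymetry,
    gyre circulation, surface temperature and irradiance) so that idealized
    twin experiments comparing the two interpolators run without external data,
    plus evaluation metrics (normalized cost function, MAE, RMSE, similarity
    coefficient) and chlorophyll-to-carbon-to-nitrogen conversion utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
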