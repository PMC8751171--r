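# mslur — multiscale land use regression for intraurban PM2.5

`mslur` implements a two-stage exposure-modelling workflow for fine
particulate matter (PM2.5) in compact cities, where concentrations vary from
the regional scale down to individual street canyons.

**City scale.** Seasonal station PM2.5 is calibrated against satellite
aerosol optical depth (AOD) and circular-buffer predictors — land-use areal
fractions, road line densities, bus-stop counts, population, buffer-averaged
frontal area index (FAI), roughness length, kriged meteorology and sounding
indices — using geographically and temporally weighted regression (GTWR):

    PM2.5_ij ~ (a0 + b_ij) + (a1 + b_ij) AOD_ij + a2_ij P0_ij + ... + e

with weights `w = exp(-(d_space^2 + lambda d_time^2)/h^2)`, AOD forced into
the model, the buffer radius of each predictor family chosen by the
distance-decay correlation method, and stepwise screening under the rules
*p < 0.05 for every retained term* and *VIF < 3*. Bandwidths minimise AICc;
skill is reported as leave-one-out CV R².

**Neighbourhood scale.** One-second pedestrian-backpack PM2.5 tracks are
corrected for hygroscopic over-reading (`CF = 1 + 0.25 RH^2/(1-RH)`,
`pm = raw/CF`), background-adjusted against the fixed monitor, and expressed
as site-relative deviations ΔPM2.5. These are regressed (within-site OLS,
same screening rules) on sky view factor, point-based FAI with distance
decay `w(l) = ((R-l)/R)^2`, `R = 200 m`, and eight road-segment centrality /
space-syntax metrics. The Δ layer is predicted only on road-corridor cells
inside the training predictor ranges (no extrapolation) and added onto the
annual city-scale map.

Because real monitoring, satellite and mobile campaigns are not
redistributable, the package ships a seeded synthetic-city generator
(`generate_scene()`, `simulate_truth()`, `sample_observations()`) whose
statistical structure matches what the two-stage analysis assumes, so the
whole pipeline is testable end to end.

## Worked example

```r
library(mslur)
cfg <- default_city_config(seed = 1)   # 2 km desk-scale city, 10 m cells
res <- lur_pipeline(cfg)               # scene -> truth -> obs -> ... -> maps

res$radii_sel$chosen["RES", ]          # distance-decay buffer choice
#>     family radius     col
#> RES    RES    300 RES_300

res$gtwr_fits$winter
#> GTWR fit: pm25 ~ AOD + RES_300 + MSLP + RD3_50 + LONG
#>   kernel gaussian, h = 1e+06 m, lambda = 0
#>   n = 16, tr(S) = 6.00, R2 = 0.803, adj R2 = 0.704, AICc = 99.39

res$delta_model
#> delta-PM2.5 MLR: FAI_POINT + CONNECT + SVF
#>   n = 9000, R2 = 0.543, adj R2 = 0.543
#>              coef          p   vif
#> FAI_POINT 103.800  0.000e+00 2.211
#> CONNECT     1.137 6.846e-198 1.026
#> SVF        -9.867 3.006e-187 2.183
```

The buffer screen recovers the 300 m residential radius that generated the
synthetic field; the seasonal GTWR models keep AOD plus a handful of
screened predictors (all p < 0.05, all VIF < 3); and the street-level model
finds the canyon signature — negative sky-view-factor effect (more open sky,
lower PM2.5), positive point-FAI effect (denser frontal area, higher PM2.5).
`plot_map(res$map_final)` draws the combined surface with the 35 µg/m³
air-quality-objective contour.

## Package layout

- `R/raster.R`, `R/vector.R` — grid/vector containers, plain-text I/O,
  the shared cell-indexing convention, bilinear resampling, FFT focal sums
- `R/synthetic_city.R` — scene generator, generative truth, observation
  sampling (stations, AOD overpasses with QA, weather, mobile tracks)
- `R/aod_met.R` — AOD QA filter, Terra/Aqua merge, ordinary kriging
- `R/morphology.R` — FAI (silhouette occlusion), point-FAI, SVF, roughness
- `R/network.R` — segment centrality (primal, length-weighted) and
  space-syntax metrics (dual graph)
- `R/predictors.R`, `R/selection.R` — buffer predictor extraction and table
  assembly; distance-decay and stepwise screening
- `R/gtwr.R` — the `gtwr()` model class (print/summary/coef/predict/...),
  bandwidth selection, LOOCV, surface prediction
- `R/neighborhood.R`, `R/mapping.R` — mobile-data calibration, ΔPM2.5
  modelling, seasonal/annual/delta/final maps
- `R/pipeline.R` — `lur_pipeline()` / `run_pipeline()` with manifests
- `vignettes/multiscale-lur.Rmd` — the methods vignette
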