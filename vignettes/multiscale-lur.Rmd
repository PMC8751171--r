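---
title: "Multiscale land use regression for intraurban PM2.5: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale land use regression for intraurban PM2.5}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mslur)
```

## The problem

PM2.5 exposure in compact cities varies on two very different scales. At the
city scale, regional transport, land-use patterns, traffic and meteorology
shape a smooth concentration field that sparse regulatory monitors sample
well, and that satellite aerosol optical depth (AOD) proxies over space. At
the neighbourhood scale, street canyons, building clusters and traffic on
individual segments create deviations of several µg/m³ over tens of metres
that neither the monitors nor a 1 km AOD pixel can see. `mslur` models the
two scales separately and combines them:

1. **City stage.** Seasonal station means are regressed on AOD (forced) and
   screened buffer predictors with *geographically and temporally weighted
   regression* (GTWR): at every observation a weighted least-squares fit is
   solved with weights decaying in the combined distance
   `d² = d²_space + λ·d²_time`, giving location/time-varying coefficients.
2. **Neighbourhood stage.** One-second pedestrian measurements, corrected
   for humidity and background drift and expressed as site-relative
   deviations ΔPM2.5, are regressed on point-scale morphology (sky view
   factor, point-based frontal area index) and road-segment network metrics.
   The fitted Δ surface is valid only in road space and only inside the
   training predictor ranges, and is added to the city map.

## Models and key formulas

**Humidity correction.** Light-scattering personal monitors over-read when
droplets grow on particles. Raw readings are divided by
`CF = 1 + 0.25·RH²/(1−RH)` (RH a fraction; the form is singular at RH = 1,
which is rejected). The synthetic generator inflates the true field by the
same factor, so the pair is verifiable by construction.

**Background adjustment.** `pm_adj = pm − (bg(hour) − mean bg)` removes
hour-to-hour and day-to-day drift using the fixed background monitor while
preserving the campaign mean exactly (the mean is sample-weighted). A
multiplicative variant is available (`ratio = TRUE`).

**Frontal area index.** `FAI = Σ_θ [A_F(θ)/A_T]·P(θ)` over the eight
principal wind directions, with `A_F(θ)` the area of the *merged* building
silhouette perpendicular to the flow — overlapping silhouettes are merged at
each height slab rather than summed, reading "total projected area" as the
silhouette of the group. The point-based variant integrates the
direction-averaged frontal-area density over a circle of `R = 200 m` with
the decay weight `w(l) = ((R−l)/R)^c`, `c = 2`, and normalises by the circle
area. The per-building density (height × mean projected width / footprint
area) is defined so that integrating it over a footprint recovers the
building's frontal area, which makes the decayed integral consistent with
the lot-based index (the two agree within 1 % when the decay is switched
off).

**Sky view factor.** The printed source formula for the horizon-scan SVF is
typographically corrupted; the package implements the standard horizon-scan
for a horizontal viewpoint: along each of `n` azimuths the horizon elevation
`φ` is the maximum of `atan((z−z0)/l)` up to distance `d`, and
`SVF = mean(cos²φ)`. This is validated against an independent Monte-Carlo
hemisphere ray-casting oracle (10⁵ cosine-weighted rays, agreement < 0.01).
The azimuth count matters near sharp canyon walls: 16 azimuths suffice for
mapping, while oracle comparisons use 256.

**Network metrics.** Centrality (normalized straightness, betweenness,
closeness) is computed on the primal road graph with length-weighted
shortest paths, evaluated at segment midpoints inserted as vertices;
betweenness counts midpoint-pair geodesics by shortest-path-counting on the
geodesic DAG (exact under ties) and is normalised by `(N−1)(N−2)/2` per
component. Space syntax (connectivity, control, mean depth, global/local
integration with the diamond `D_k` normalisation, local radius 3) is
computed on the segment dual graph — a segment-adjacency approximation of an
axial map, chosen because axial-line derivation is tool-bound and
unspecified. Both families are tested against brute-force path enumeration
on small random graphs.

**Buffer predictors.** All circular-buffer quantities use the
cell-center-in-circle rule at the 10 m working resolution (deterministic, no
partial-cell weighting; quantisation error < 1 % for radii ≥ 100 m).
Whole-grid evaluators apply the identical rule at every cell center (FFT
focal sums for raster sources, exact circular stamps for point and centroid
sources), and the station predictor table samples those same surfaces — so a
map prediction at a calibration station's cell reproduces the calibration
row exactly. Stations are placed on cell centers. GCR is derived from the
open-space/greening class; the line-density and buffer-FAI surfaces
accumulate geometry per cell (lengths; unoccluded frontal-area density),
which differs from the exact-geometry single-point operations by the cell
quantisation only.

**Screening.** Each spatial family is first reduced to one radius by the
distance-decay method (largest |Pearson r| against the response; ties to the
smallest radius; the pipeline correlates against the within-season response
because the seasonal background is common to all radius candidates and only
dilutes the ranking). Stepwise selection is bidirectional with |t|-ordered
entry: a candidate enters only if its p-value is below 0.05 *after* entry
and every VIF stays below 3; non-forced terms that lose significance are
removed. AOD is forced at the city stage. Screening runs once on the pooled
station × season table (n ≈ 64) — per-season screening is not supportable at
16 rows per season — while the GTWR models are then fitted per season on the
common subset (terms constant within a season, e.g. sounding indices, act
through the seasonal intercept and are dropped from the seasonal designs).

**GTWR.** Gaussian kernel by default (bisquare available), additive
space–time metric with ratio λ, AICc
`n·ln(RSS/n) + n·ln 2π + n(n + tr S)/(n − 2 − tr S)` with `tr S` effective
parameters from the local hat rows, bandwidth by grid search plus
golden-section refinement, and leave-one-out CV with the self-weight zeroed.
In the flat-kernel limit (`h → ∞`, `λ → 0`) every local fit equals global
OLS, which the tests assert to 10⁻⁶.

**ΔPM2.5 model.** Because the response is defined relative to the site mean,
the predictors enter the model the same way: each candidate is centred on
its site mean (within-site estimator). Leaving the predictors raw would let
between-site predictor variance — which carries no response variance by
construction — attenuate every coefficient toward zero. For mapping, the Δ
layer references each retained predictor to its mean over the valid road
cells, so the valid-cell mean of the layer equals the near-zero intercept.
The layer is masked to the road corridor and to the training range of every
retained predictor (no extrapolation), and added to the city map with a
physical floor at 0 µg/m³.

**Annual combination.** The annual surface is the day-count-weighted mean of
the seasonal surfaces, renormalised over the seasons valid at each cell; a
cell valid in no season stays nodata. Annual skill is computed over pooled
seasonal fitted/observed pairs.

## The synthetic study area

The generator emulates, at desk scale, the statistical structure the
analysis assumes — not any real city's geography:

* a 2 km × 2 km scene at 10 m resolution (the extent must be ≥ 4× the
  largest buffer radius, so the default radius series is truncated at
  500 m; `pipeline_config()` itself defaults to the full ten-radius series
  50–2000 m used with full-size studies);
* a five-class land-use mosaic (residential 0.30, commercial 0.10,
  industrial 0.10, government 0.10, open/greening 0.40, each within ±2 %)
  with 100 m patch correlation length;
* a jittered grid street network spanning all five road classes; ~1200
  buildings fronting the streets with block-scale density contrast, so
  street canyons and open streets coexist;
* 16 ambient monitors on cell centers, off the road corridor (as routine
  networks site them), 8 weather stations, 120 bus stops, a population
  raster (mean 6700 persons/km²);
* truth field = seasonal AR(1) background (means 22/15/28/35 µg/m³,
  ρ = 0.6, σ = 2.5) + linear trend (−2.0, +1.5 µg/m³ per km) + a residential
  source of 20 µg/m³ per unit areal fraction at a **300 m** radius + on road
  cells only, morphology effects `−10·(SVF−1) + 40·FAI_point`;
* AOD = (pixel-mean city-scale field − b)/a + noise at 400 m pixels
  (a = 50 µg/m³ per AOD unit, σ_AOD = 0.05), with a seeded cloud process
  (25 % cloudy, "possibly cloudy" fringe) and a coastal retention band along
  the southern edge; the pixel is deliberately coarse relative to the
  land-use detail, mirroring the 1 km : 10 m ratio of the satellite and
  land-use products, and the column retrieval does not see sub-pixel
  street-canyon deviations;
* daily station noise of 9 µg/m³ — within-season daily variability the
  seasonal model is not meant to explain — giving seasonal-mean sampling
  error ≈ 2.3 µg/m³, comparable to seasonal LUR residuals on real data;
* a mobile campaign of 10 sites × 900 one-second samples at 0.8 m/s along
  the streets, three daily slots, RH 0.25–0.92 inflating the raw readings
  through the correction factor, σ_mobile = 1.5 µg/m³. Sites are road nodes
  in districts where the city-scale field is locally flat but morphology is
  diverse, mirroring purposeful representative-site selection — without
  this, within-site land-use variation confounds the street-level effects.

Every stochastic draw flows from the configured seed (scene, truth and
observations use `seed`, `seed+1`, `seed+2`), so reruns are bit-identical
and `run_pipeline()` manifests reproduce exactly.

**What passing tests do and do not show.** The generator has flat terrain,
axis-aligned rectangular buildings, linear class–concentration links,
Gaussian noise, and a single active land-use class; recovery there
demonstrates that the estimators are implemented correctly and are
statistically consistent under the assumed structure, not that the model
form is adequate for any real city.

## Numerical choices and degenerate inputs

* Kriging uses an exponential variogram, zero nugget, fitted by weighted
  least squares to the empirical semivariogram (weights N(h)/γ²); the
  surface interpolates stations exactly and weights sum to one. Degenerate
  fits (constant fields, range collapsing or exploding) fall back to
  inverse-distance weighting with a warning; kriged wind speed and rainfall
  are floored at zero with the clip count recorded. Meteorology is
  interpolated daily.
* Singular local GTWR systems receive a relative ridge of 10⁻⁸ with a
  warning; AICc candidates with `tr S ≥ n − 2` are skipped.
* Bilinear AOD resampling renormalises weights over valid neighbours,
  clamps at the outermost cell centers, and preserves source-center values.
* Distance-decay ties break to the smallest radius; constant families are
  dropped with a message; stepwise entry order is decreasing |t|, making
  selection invariant to row and column order.
* Mobile samples farther than 25 m from any segment are dropped and
  counted; sites need ≥ 30 samples (≥ 2 strictly).
* The point-FAI integral is discretised at `R/100` by default and refuses
  steps coarser than `R/10`; halving the default step moves results by well
  under 1 %.

## Known limitations

* The GTWR seasonal fits at desk scale have 16 rows; bandwidth selection
  then almost always prefers the global limit, which is the correct answer
  under the spatially constant generative coefficients but exercises the
  local machinery only weakly (the unit tests cover varying-coefficient
  recovery separately at n = 300–400).
* With ~25 screened candidates at α = 0.05 and no multiplicity control —
  the literal screening rule — stepwise admits a median of ~2 chance
  inclusions beyond the true active set on permuted or clean runs alike;
  the acceptance suite documents this rather than hiding it.
* SVF and point-FAI both measure the openness/density axis (r ≈ −0.5); at
  desk scale the screen often retains one of the two, and the split of the
  shared effect between them is not identifiable. The composite density
  effect (dense-enclosed minus open-sparse prediction) is the stable
  summary.
* Raster I/O is plain-text ESRI ASCII by design (portable, diffable,
  version-controllable); for very large rasters a binary format would be
  preferable.
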