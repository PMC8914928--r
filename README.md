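# spatgran

Spatial analysis of outdoor sensor networks: optimal areal-unit selection
by Pareto-ranked spatial autocorrelation criteria, and Kriging
interpolation of pollutant fields.

## The problem

Air-quality monitors report point measurements, but planners reason about
areas. Any map of "AQI by region" first aggregates sensors into areal
units, and the conclusions change with the unit size — the modifiable
areal unit problem (MAUP). `spatgran` treats the choice of spatial
granularity as a two-criterion optimisation:

* **Global Moran's I** (GM), to maximise — the overall spatial
  autocorrelation of the aggregated values,

  I = n / (ΣᵢΣⱼ wᵢⱼ) · ΣᵢΣⱼ wᵢⱼ(yᵢ−ȳ)(yⱼ−ȳ) / Σᵢ(yᵢ−ȳ)²

* **CV of Local Moran's I** (LMCV), to minimise — the instability of the
  per-unit decomposition Iᵢ = (yᵢ−ȳ)·Σⱼ wᵢⱼ(yⱼ−ȳ) / (Σᵢ(yᵢ−ȳ)²/n),
  summarised as sd(Iᵢ)/|mean(Iᵢ)|.

Candidate hexagon side lengths (e.g. 100–500 km for a continental
analysis) are scored on (GM, LMCV) over first-order contiguity weights and
Pareto-ranked: a scale is optimal when no other scale is at least as good
on both criteria and strictly better on one. Significance of the Moran
statistics is assessed by seeded permutation (pseudo-significance) tests.

For mapping, the package implements the standard geostatistical workflow:
normalise the values (automatic transform selection by Shapiro–Wilk W),
estimate the empirical semivariogram (Matheron), fit an exponential /
spherical / Gaussian model by weighted least squares, and predict on a
grid by ordinary Kriging, Ẑ(s₀) = Σᵢ λᵢ Z(sᵢ) with Σλᵢ = 1. Indicator
Kriging of threshold indicators 1{z > t} yields exceedance-probability
surfaces (e.g. P(AQI > 50), the Good/Moderate boundary). AQI itself is
computed from US-EPA breakpoint tables by the piecewise-linear index
formula and classified into the six levels of concern.

## Worked example

```r
library(spatgran)

# a synthetic monitoring network: 250 sensors over ~1000x800 km,
# exponential covariance with a 150 km range
pd <- simulate_field(field_spec(n_points = 250, range_km = 150,
                                nugget = 0.05, seed = 1))

ev <- evaluate_scales(pd, scales = c(50, 100, 150, 200, 300, 400),
                      permutations = 199, seed = 1)
ev
#> Candidate areal-unit scales (GM: Global Moran's I, maximise; LMCV: CV of local Moran's I, minimise)
#>  scale        GM   LMCV n_cells p_pseudo frontier_rank
#>     50  0.535184  1.499     110    0.005             1
#>    100  0.357567  1.317      39    0.005             1
#>    150  0.299300  1.769      20    0.065             2
#>    200  0.189456  2.552      12    0.345             3
#>    300 -0.017342 20.157       9    0.965             4
#>    400 -0.008252 42.036       7    0.995             4
#> Pareto-optimal scale(s): 50, 100 km
```

Aggregating beyond the field's correlation range erodes the spatial
signal (GM falls towards its null value) while making the local structure
less stable (LMCV explodes), so the coarse scales are dominated. Two
scales share the first frontier — 50 km carries the stronger global
autocorrelation (GM 0.54, pseudo-p 0.005 over 110 hexagons) while 100 km
has the steadier local structure (lower LMCV) — a genuine trade-off the
method deliberately leaves to the analyst.

```r
# interpolation workflow at the chosen support
res <- run_krige(run_config(grid_n = 25, threshold = 60, seed = 1,
                            out_dir = "out"), data = pd)
res$variogram
#> <variogram_model> exponential: nugget = 0.2709, partial sill = 2.027, range = 802.7 km
head(read.csv("out/exceedance.csv"))   # P(value > 60) per grid node, in [0, 1]
```

Real data enter through `read_epa_daily()` (the US-EPA 28-field daily CSV
layout plus a site-coordinates sidecar), `temporal_reduce()` (e.g. annual
mean AQI per monitor) and `project_to_planar()`; `compute_aqi()` /
`classify_aqi()` convert concentrations to index values where the AQI
column is not used directly. A thin CLI with subcommands
`simulate | granularity | lisa | krige | aqi` ships in `exec/spatgran`.

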