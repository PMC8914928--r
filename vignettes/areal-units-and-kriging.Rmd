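---
title: "Choosing areal units and mapping sensor fields: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choosing areal units and mapping sensor fields: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatgran)
```

## The model

`spatgran` analyses point-referenced sensor observations in two stages: a
*granularity* stage that chooses the size of the areal unit used to
aggregate sensors, and an *interpolation* stage that maps the field
between sensors.

### Granularity as a multicriteria problem

Aggregating points into areal units always imposes a scale, and the
statistics computed on the aggregated data change with that scale (the
modifiable areal unit problem). Rather than fixing the scale by
convention, each candidate hexagon side length $x$ is scored by an
objective vector $\Phi(x) = (\mathrm{GM}(x), \mathrm{LMCV}(x))$:

* $\mathrm{GM}$, Global Moran's I of the aggregated cell values over
  first-order contiguity weights,
  $$I = \frac{n}{\sum_i\sum_j w_{ij}}
        \frac{\sum_i\sum_j w_{ij}(y_i-\bar y)(y_j-\bar y)}
             {\sum_i (y_i-\bar y)^2},$$
  to be maximised: higher values mean the units capture coherent spatial
  structure rather than noise.
* $\mathrm{LMCV}$, the coefficient of variation of the local Moran values
  $$I_i = \frac{(y_i-\bar y)\sum_j w_{ij}(y_j-\bar y)}
               {\sum_i (y_i-\bar y)^2 / n},$$
  to be minimised: a scale whose local indicators vary wildly across the
  map yields unstable, hard-to-interpret local patterns.

A scale $x_i$ *dominates* $x_j$ when it is at least as good on both
objectives and strictly better on one. Iteratively peeling non-dominated
sets gives Pareto frontiers; the rank-1 frontier is the optimal set. When
it contains several scales the package returns all of them — the two
criteria are genuinely conflicting and the final pick is the analyst's.

The two objectives enter dominance on their raw scales. Min–max rescaling
of LMCV into the span of the GM values is available in
`plot.granularity_eval(normalize = TRUE)` purely for display: a monotone
per-objective transform cannot change any dominance relation.

### Assumptions

The Moran statistics assume a fixed support (the hex layer), exchangeable
values under the null, and enough non-empty cells to be meaningful
(`evaluate_scales()` drops scales with fewer than 3, or with an
all-isolated contiguity graph, with a warning). The values are treated as
a snapshot — one value per cell, typically an annual mean AQI per monitor
aggregated to cells; no temporal correlation is modelled.

## Decisions where the design was open

* **Weights.** Binary contiguity defines the neighbour relation; the
  experiments use row-standardised weights, and both styles are exposed
  (`style = "row"` default). On a regular hexagon grid edge- and
  vertex-contiguity coincide, so rook equals queen.
* **Pseudo-significance.** Permutation inference: the global test
  permutes the whole value vector; the local test holds $y_i$ fixed and
  permutes the remaining values among the other cells (conditional
  scheme). $p = (1 + \#\{|I^{perm}| \ge |I^{obs}|\})/(1+B)$, two-sided,
  $B = 999$ by default, always seeded.
* **CV definition.** $\mathrm{sd}(I_i)/|\mathrm{mean}(I_i)|$ with the
  sample (n−1) standard deviation. The absolute value keeps the objective
  well defined when the mean is near zero; an exactly zero mean returns
  `Inf` with a warning rather than `NaN`.
* **Isolated cells** keep $I_i = 0$ and stay in $n$, but note that a
  row-standardised matrix with empty rows has $S_0 < n$, so the exact
  decomposition identity $\mathrm{mean}(I_i) = I$ is stated — and tested —
  over layers whose cells are all connected.
* **Grid geometry.** Flat-top regular hexagons, anchored with a cell
  centre at the lower-left corner of the bounding box. The anchor is a
  parameter (`origin`) because grid placement is itself a MAUP-relevant
  choice. Points on a shared edge go to the equidistant cell whose centre
  is lexicographically smallest — a deterministic partition. Cells are
  not clipped to coastlines or borders.
* **Projection.** Sensors arrive in lon/lat; analysis runs in a planar km
  frame under an equirectangular projection about the data centroid
  (WGS84 equatorial radius). At the regional scales involved this keeps
  distances adequately true; cell areas are approximate, and the
  projection is exactly invertible for writing maps back in lon/lat.

## The interpolation stage

The workflow is normalise → variogram → ordinary Kriging → back-transform.

* **Normalisation** selects among identity, shifted log, shifted square
  root, Box–Cox, Yeo–Johnson and a rank-based ordered-quantile map,
  maximising the Shapiro–Wilk W of the transformed sample; every
  transform carries an exact inverse on the observed range (the
  ordered-quantile map inverts by monotone interpolation, exact at
  observed values). Fewer than 10 values, or constant input, fall back to
  identity with a warning.
* **Empirical variogram**: Matheron's estimator,
  $\hat\gamma(h) = \frac{1}{2|N(h)|}\sum (z_i - z_j)^2$, default 15 lags
  to half the maximum pairwise distance. Empty bins are dropped with a
  warning; bins with fewer than 5 pairs are flagged.
* **Model fitting**: weighted least squares with pair counts as weights,
  for exponential $\gamma(h) = c_0 + c\,(1 - e^{-h/a})$, spherical and
  Gaussian families, under box constraints $c_0, c \ge 0$ and
  $a \in (0, 3\,h_{max}]$ — beyond the sampled lags the range is not
  identifiable, so it is bounded there. The objective is multimodal in
  degenerate cases, so the fit multi-starts L-BFGS-B from three range
  guesses and polishes with Nelder–Mead, keeping the best solution. A
  flat empirical variogram returns $c \approx 0$ with a warning (pure
  nugget; range meaningless).
* **Ordinary Kriging** solves, per target, the semivariance system
  augmented with the unbiasedness constraint $\sum_i \lambda_i = 1$ via a
  Lagrange multiplier; the estimate is $\sum_i \lambda_i Z(s_i)$ and the
  kriging variance $\sum_i \lambda_i \gamma_{i0} + \mu$. The mean is
  unknown but constant. $\gamma(0) = 0$ by convention, so predictions at
  data locations reproduce the observations (exactly, with zero nugget).
  Duplicate locations make the system singular and raise an instructive
  error. A local-neighbourhood mode (`neighbors = k`) solves the system
  over the k nearest points per target for large n. Kriging variance is
  reported on the transformed scale only; back-transforming a variance
  through a nonlinear map would require assumptions the package does not
  impose (documented limitation).
* **Indicator Kriging** kriges $1\{z > t\}$ with its own fitted
  variogram and clips estimates into $[0,1]$; the default showcase
  threshold is AQI 50, the Good/Moderate boundary. If every observation
  falls on one side of $t$ the surface is the constant 0 or 1 with a
  warning.

## AQI computation

The index is piecewise linear between breakpoints:
$I_P = \frac{I_{Hi}-I_{LO}}{BP_{Hi}-BP_{LO}}(C_P - BP_{LO}) + I_{LO}$,
where $C_P$ is the concentration *truncated* (not rounded) to the
pollutant's stated decimals, and the final index is rounded half-up to an
integer so it lands in the integer category ranges (Good 0–50 …
Hazardous 301+). The packaged breakpoint file carries the published
US-EPA guidance values for O3/NO2/SO2/CO and is user-overridable; the
structural identities (index hits $I_{LO}$/$I_{Hi}$ exactly at row
edges, monotonicity, category partition of $[0,\infty)$) hold for any
valid table and are what the tests assert. The EPA daily files already
carry per-pollutant AQI columns; the reader uses them by default
(`value = "aqi"`) or recomputes from concentrations (`value = "mean"`
plus `compute_aqi()`), since either convention appears in practice.

## What the synthetic generator emulates — and what it does not

`simulate_field()` draws sensor locations uniformly over a planar
rectangle and values from a stationary Gaussian random field with
exponential (or Gaussian) covariance $C(h) = \sigma^2 e^{-h/a}$ plus
nugget, via dense Cholesky factorisation (capped at 3000 points). The
defaults — 1000×800 km, 200 sensors, range 150 km, unit sill, 10%
nugget, mean 60 — emulate a regional pollutant surface with moderate
spatial structure at an AQI-like level. Degenerate fixtures (constant
field, alternating checkerboard lattice) provide exact ground truth for
the zero-variance error path and for $I = -1$ negative autocorrelation.

Real monitoring networks differ in ways the generator does not model:
sensors cluster in cities rather than scattering uniformly; pollutant
fields are non-stationary (trends with elevation, coastlines, emission
sources) and non-Gaussian after aggregation; and AQI values are bounded
and discretised. Passing tests therefore demonstrate correctness of the
*method* under its own assumptions, not field performance on EPA data.

## Problem sizes and numerical choices

The test and acceptance suites run, by the package's choice, at desk
scale: layers of roughly 30–110 cells, permutation counts of 99–999,
20-seed replication for stochastic properties, and kriging problems of
up to a few hundred targets. The variogram parameter-recovery study uses
400 points with a 100 km range on a 2000×1600 km domain: a domain many
effective ranges (3a ≈ 300 km) across is a statistical prerequisite for
the range to be identifiable from a single realisation — on a domain
only ~2–3 effective ranges wide the empirical variogram is dominated by
realisation-level noise and any estimator scatters badly. Success is
counted as a fitted range within a factor of 2 of truth.

Tolerances follow the arithmetic: exact identities (Moran hand cases,
LISA decomposition, weight sums) are asserted near machine precision
(1e-10 or better); cross-implementation agreement at 1e-6; stochastic
properties as rates over fixed-seed replicates. All randomness flows
through explicit seeds; seeded routines save and restore the session RNG
state so library calls do not disturb user code.

## Known limitations

* The equirectangular projection is not equal-area; at continental
  extents cell areas drift by a few percent. An equal-area hook is the
  natural extension.
* Kriging variance is not back-transformed.
* The candidate scale set is user-supplied; there is no automatic scale
  search, and no tiebreak when several scales share the first frontier.
* Dense-matrix kriging and simulation cap practical sizes at a few
  thousand points; the local-neighbourhood mode relaxes this for
  prediction.
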