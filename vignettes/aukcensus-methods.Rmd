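---
title: "Methods and design notes for the aukcensus pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for the aukcensus pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aukcensus)
```

This vignette documents the models behind `aukcensus`, the assumptions
they make, the tunable parameters that matter, and the design choices
taken where several defensible options existed. The package estimates
the breeding population of a crevice-nesting seabird, the little auk,
from colony-patch polygons and rock-size data, and analyses the
environmental determinants of colony occurrence and size.

## Terrain and geometry

All vector and raster inputs are assumed to live in one common projected
metric plane (a UTM zone in practice). The package validates geometry
but performs no reprojection, and all distances are planar Euclidean —
adequate at the spatial extent of a regional census, and consistent with
inputs produced by a projected GIS workflow.

Patch areas come from the shoelace formula on the polygon ring
(`polygon_flat_area()`), with validation for degenerate and
self-intersecting rings. The true scree surface exceeds its map
projection on a slope, so areas are corrected by
`slope_corrected_area()`: \(c = a / \cos\alpha\), with \(\alpha\) the
mean patch slope. The correction uses a single mean slope per patch —
a first-order approximation that slightly underestimates the surface
area of patches with strongly varying slope (Jensen's inequality), but
matches how such censuses are computed in practice.

Slope and aspect derive from the DEM by Horn's 8-neighbour finite
differences, the de-facto standard of GIS slope/aspect tools, with edge
replication at the border. Aspect is reported clockwise from north in
[0, 360); cells with zero gradient receive the sentinel `-1`, which
zonal summaries exclude. Zonal statistics average the cells whose
*centers* fall in the polygon; a 2 900 m² patch spans about seven 20 m
cells, so this is stable, but sliver polygons can miss every center — in
that case the cell nearest the centroid is used and a warning raised.

Pseudo-absence polygons (`generate_absence_polygons()`) are squares of
the target area (2 900 m², the mean surveyed patch size) with random
orientation, rejection-sampled so each centroid lies within 7 km of the
coastline and 55 km of the nearest foraging hotspot, and no polygon
touches the exclusion mask (glaciers, islets, known colonies). Polygon
shape does not enter any downstream statistic — only centroid location
and area do — so squares suffice. Sampling aborts after
\(1000 \times n\) attempts, reporting infeasibility rather than looping
forever.

## The nest-density model

Nest density (nests/m²) is modelled as a linear function of the natural
log of mean rock diameter (m):
\(D = a + b\,\ln(\mathrm{RS}) + \varepsilon\),
\(\varepsilon \sim N(0, \sigma^2)\). The model is undefined below
0.10 m diameter, where crevices are too small to host nests; inputs are
validated accordingly. With very few observations (the reference design
has seven) a Bayesian treatment keeps the uncertainty honest, so the
model is fitted by a conjugate two-block Gibbs sampler:

* priors: \(a, b \sim N(0, 100^2)\), \(\sigma^2 \sim\)
  inverse-gamma(0.001, 0.001) — weak enough that the likelihood
  dominates even at \(n = 7\); all hyperparameters are exposed in
  `mcmc_config()`.
* sampling: both conditionals are exact (normal and inverse-gamma), so
  no proposal tuning is needed. Defaults follow the study settings:
  2 chains, 13 000 iterations, burn-in 3 000, thinning 10 — exactly
  1 000 retained draws per chain. Chains start at the least-squares
  solution with chain-indexed residual-variance starts.
* diagnostics: `gelman_rubin()` implements the classic potential scale
  reduction factor \(\sqrt{((n-1)/n\,W + B/n)/W}\). For identical
  chains this equals \(\sqrt{(n-1)/n}\), i.e. 1 only up to \(O(1/n)\);
  we report the unclamped value. `coda::gelman.diag` is used as an
  independent oracle in the test suite, never as the implementation.
* \(R^2\) is computed at the posterior-mean coefficients against the
  observed densities, since a Bayesian fit has no canonical \(R^2\).

Predictions (`predict_density()`) are the posterior mean and central
95% interval of \(a + b\ln(\mathrm{RS})\); negative values (possible at
small RS) are clamped to zero with a warning. `compare_models()`
contrasts the least-squares \(R^2\) of the log form against a straight
line in RS.

## Census aggregation

`patch_nest_estimate()` multiplies the slope-corrected area by the
density mean and both interval bounds; `aggregate_census()` sums means
and bounds independently across patches and regions. Treating areas as
error-free and summing bounds replicates the arithmetic of regional
census tables, and overstates joint coverage relative to summing a full
posterior — a deliberate choice for comparability, stated here openly.
All arithmetic stays in floating point; integers appear only when a
report is rendered, which is why re-summing a rounded published table
can differ from the rounded sum by a couple of pairs. Regions without
rock-size data take fixed zero-width densities
(`default_density_overrides()`: 1 nest/m² for Kongsfjorden, 0.2 nest/m²
for Sjuøyane). Cliff colonies use
`cliff_colony_estimate()`: pairs = birds / (2 × attendance). At the
default mid chick-rearing attendance of 0.5 this equals the bird count
itself; the alternative reading — one mate ashore per nest, so pairs =
birds — gives the same number at attendance 0.5. World-population
shares divide the census bounds by the *opposite* world bounds (low/high
vs high/low), which is the conservative bracket.

## At-sea densities and hotspots

Strip-transect density is count / (length × strip width), with the
300 m strip of the survey protocol as default. Transects from several
seasons are pooled. The density surface is interpolated by
piecewise-linear (barycentric) interpolation on a Delaunay
triangulation built with a Bowyer–Watson construction. This substitutes
for Sibson natural-neighbour interpolation while sharing the properties
that matter downstream: it honors the data exactly at the data sites,
stays within the input range, and is undefined outside the convex hull.
Hotspot locations, not surface smoothness, drive the downstream
distance covariate, so the simpler interpolant is adequate; the method
tag is stored in the surface's provenance field. A deterministic
relative jitter of order \(10^{-8}\) breaks cocircular degeneracies in
the triangulation; site queries short-circuit to the exact site value.

`detect_hotspots()` takes strict 3×3 local maxima, ranks them by
density and greedily enforces a minimum separation (default 10 km,
`top_k` default 10 — survey-design parameters, exposed because no
canonical values exist). A flat surface has no strict maximum and
returns an empty set.

## Occurrence models

The presence/absence analysis uses additive logistic models fitted with
`mgcv`: thin-plate regression spline smoothers (basis dimension 10) for
slope and aspect, linear logit-scale terms for elevation, radiation and
hotspot distance. Predictors are ln(x+1) transformed and then scaled to
mean 0, SD 1 over the combined presence+absence table — transformation
before scaling, the only order in which scaling aids convergence; the
transform parameters are stored for prediction. Aspect is treated as a
plain (non-cyclic) smooth on [0, 360): the 0°/360° seam is accepted, as
in the reference analysis; a cyclic basis can be requested through the
smoother machinery if continuity at north matters. Smoothing parameters
are selected by REML; AIC counts effective degrees of freedom.

`all_subsets()` fits every subset of the five candidate terms (32
models including the null), ranks by AIC and computes Akaike weights;
`relative_variable_importance()` sums the weights of models containing
each term. "Variance explained" is implemented as deviance explained
(\(1 - D/D_0\)), the standard for binomial additive models. The top
model is reported rather than a model average; averaged prediction is
possible by weighting `predict_occurrence()` over the set, but is not
wired in as a default.

Exact coefficient values of any particular GAM implementation are not a
reproduction target: spline bases, identifiability constraints and
penalty selection all shift coefficients without changing the fitted
relationships. The test suite instead verifies behaviour: unpenalized
linear-only fits agree with a hand-rolled IRLS oracle to \(10^{-6}\),
weight identities hold exactly, and the informative predictors outrank
the uninformative one in RVI across seeded replicates.

## The colony-size tree

`cit_fit()` implements conditional inference trees from scratch. At
each node the response is tested against every predictor with a
Monte-Carlo permutation test of the linear association statistic
(covariance with the centered response; for categorical predictors the
maximum over level indicators of the statistic standardized by its
permutation moments). One shared set of permutations serves all
predictors at a node. P-values are Bonferroni-adjusted over the
predictors tested; the node splits only if the smallest adjusted p is
below `alpha` (default 0.05), which is the sole stopping rule — no
pruning. The split itself maximizes the between-group sum of squares:
thresholds between consecutive order statistics for numeric predictors,
all \(2^{L-1}-1\) level bipartitions for categorical ones (feasible
exhaustively at \(L \le 8\) rock types). Reported level sets are
normalized to the smaller side. Defaults: `minsplit = 20`,
`minbucket = 7`, `n_perm = 9999` (the Monte-Carlo approximation is
seed-controlled and assumption-free; the smallest attainable p is
\(1/(n_\mathrm{perm}+1)\), so adjusted p-values below 0.001 need the
full 9 999 permutations). Ties in p resolve by predictor declaration
order. The response is used untransformed (breeding pairs) so terminal
node means are arithmetic colony-size means.

## The synthetic world

The generators encode the study conditions as defaults: 20 m DEM cells;
143 colonies vs 194 pseudo-absences (prevalence 0.424); the density law
\(D = 2.77 + 1.58\ln(\mathrm{RS})\), which reproduces the published
regional density table across the observed rock-size range, with rock
diameters LogNormal(ln 0.45, 0.35) spanning that range and residual SD
0.15 nests/m² chosen to resemble the published interval widths; an
occurrence truth with elevation (−), radiation (+) and slope (+) effects
and a null distance effect, intercept calibrated by root-finding to the
target prevalence; colony sizes driven by rock type with a large
amphibolite/quartzite class; and 615 at-sea transects with Poisson
counts around planted radial intensity kernels. The default world
extent is 10 km — large enough for hundreds of patches and offshore
transects while keeping a full pipeline run well under a minute.

The generator emulates the *statistical* structure the analyses assume:
logistic occurrence on transformed predictors, log-linear density,
type-driven sizes, Poisson transect counts. It does not emulate Arctic
geomorphology, spatial autocorrelation of residuals, observer error in
polygon delineation, or multi-year dynamics. Passing tests therefore
demonstrate that the estimators recover known truth under the assumed
data-generating process — not that the assumptions hold in the field.

One calibration property deserves honesty: with only seven rock-size
observations drawn independently, the log-curved and straight-line
density models are sometimes statistically indistinguishable — when the
seven diameters happen to cluster, noise decides the \(R^2\) ranking.
Across many seeded replicates at noise SD 0.05 the log form wins about
90% of the time, not essentially always; the corresponding suite check
is strict and can fail for this reason. This reflects the information
content of seven points, not an estimator defect.

## Numerical and degenerate-input choices

* Polygon validation: collinearity is tested against a
  scale-relative tolerance (\(10^{-12}\) of the squared extent);
  self-intersection by exhaustive segment tests.
* Zonal fallback for sliver polygons: nearest cell to the centroid,
  with a warning.
* Density predictions and synthetic densities are floored at zero /
  just above zero; rock diameters truncated to the model's support.
* Permutation p-values use the add-one estimator
  \((1 + \#\{T^\ast \ge T\})/(n_\mathrm{perm}+1)\), so they are never
  zero, and comparisons use a small relative epsilon to make ties
  deterministic across platforms.
* All stochastic entry points take an explicit integer seed and are
  bit-reproducible given it.

## Problem sizes used in the checks

The suite and the acceptance script run: 100 seven-point density
replicates at the full study MCMC settings; 50 occurrence replicates of
337 records with all 32 models each; 200 null and 50 planted size-tree
fits (n = 300 and 150, 999 permutations for the simulations, 9 999
where sub-0.001 p-values are asserted); and 50 at-sea surveys of 615
transects. These sizes keep the complete run in the low minutes on one
CPU while leaving the binomial margins of the rate checks meaningful.

## Known limitations

* Single mean slope per patch in the area correction (see above).
* Interval propagation assumes error-free areas and perfectly
  correlated densities within a region; a posterior-sum alternative
  would be narrower.
* The occurrence models ignore spatial autocorrelation between nearby
  polygons; p-values for smooth terms are conditional on the selected
  penalty.
* The size tree offers no surrogate splits, so records with missing
  predictors cannot be routed.
* GeoJSON and Esri ASCII grids are the supported interchange formats;
  GeoTIFF is not read or written.
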