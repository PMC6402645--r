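# aukcensus

Tools for estimating the breeding population of the little auk (*Alle
alle*) on the W and NW coast of Spitsbergen (Svalbard) and for analysing
the habitat determinants of where its colonies occur and how large they
grow. The little auk nests in rock crevices under scree, so nests cannot
be counted directly; the package implements the census strategy of
combining surveyed colony-patch polygons, slope-corrected areas and a
rock-size-based nest-density model, together with the occurrence and
colony-size analyses built on top of it.

The package is aimed at quantitative ecologists working on colonial
seabird censuses and habitat models; every statistical component is also
usable on its own.

## What it computes

**Census.** A colony patch with map-plane (flat) polygon area *a* and
mean slope *α* has surface area *c* = *a* / cos *α*. Its nest count is
*c* · *D̂*(RS), where nest density follows the log-linear law

  *D̂* = *a* + *b* · ln(RS),

with RS the mean rock diameter (m) of the patch. The law is fitted by a
two-chain conjugate Gibbs sampler (normal priors on the coefficients,
inverse-gamma on the residual variance; 13 000 iterations, burn-in
3 000, thinning 10 → 1 000 retained draws per chain), checked with the
Gelman–Rubin statistic, and predictions carry central 95% credible
intervals. Region totals propagate the interval bounds (areas × density
bounds, summed), regions without rock-size data use fixed conservative
densities, and vertical-cliff colonies are estimated from bird counts
via an attendance fraction (pairs = birds / (2 · attendance)).

**Occurrence.** Presence/absence of colonies (surveyed patches vs
constrained random pseudo-absence polygons) is modelled with additive
logistic models: thin-plate regression spline smoothers for slope and
aspect, linear logit-scale terms for elevation, solar radiation and
distance to the at-sea foraging hotspots, all predictors ln(x+1)
transformed and scaled. All 2^5 = 32 term subsets are fitted, ranked by
AIC, and summarized by Akaike weights and relative variable importance
(RVI = summed weights of models containing a term).

**Colony size.** A from-scratch conditional inference tree: recursive
binary partitioning where each split must pass a Monte-Carlo permutation
test of association (Bonferroni-adjusted over predictors), with
exhaustive level-subset search for the categorical rock-type predictor.

**At-sea hotspots.** Strip-transect densities (birds / (length × 300 m
strip)), an interpolated density surface (piecewise-linear on a Delaunay
triangulation), and hotspot detection as separation-filtered local
maxima.

**Synthetic data.** Seeded generators (`world_config()`,
`make_terrain()`, `make_colony_world()`, `make_transects()`,
`make_density_obs()`, `make_occurrence_records()`,
`make_size_records()`) emit every input of the pipeline with known
ground truth, so all stages are testable end to end.

## Worked example

```r
library(aukcensus)

# fit the rock-size -> nest-density law on a 7-point observation set
obs  <- make_density_obs(7, seed = 42)
post <- fit_density_model(obs, mcmc_config(seed = 42))
post
#> Bayesian nest-density model D = a + b*ln(RS), 7 obs, 2000 draws
#>   a: 2.719 (Rhat 1.000)   b: 1.364 (Rhat 1.000)   R2 0.77

round(predict_density(post, c(0.25, 0.45, 0.61)), 2)
#>   mean cri_low cri_high
#> 1 0.83    0.16     1.53
#> 2 1.63    1.38     1.89
#> 3 2.05    1.81     2.26
```

Both chains agree (R̂ ≈ 1), and predicted densities rise from ~0.8
nests/m² on 25 cm scree to ~2 nests/m² on 61 cm boulders, with the
credible interval widening where data are sparse.

Aggregating the shipped Spitsbergen survey table reproduces the census:

```r
cen <- spitsbergen_census()
patches <- data.frame(patch_id = cen$site, region = cen$area_group,
                      n_colonies = cen$n_colonies,
                      nests_mean = cen$pairs_mean,
                      nests_low = cen$pairs_lo, nests_high = cen$pairs_hi)
rep <- aggregate_census(patches)
rep
#> Colony census report
#>          region n_colonies nests_mean nests_low nests_high
#>        Bellsund         15      35814     24665      47165
#>        Hornsund         65     591891    382751     808974
#>       Isfjorden          1        135        49        227
#>    Kongsfjorden          1       3890      3890       3890
#>  NW Spitsbergen         56      91978     63136     121277
#>        Sjuoyane          5       4821      4821       4821
#> Total: 728529 (5-95% CI 479312-986354) pairs over 143 colonies; mean 5094 nests/patch

global_share(rep$total_mean, rep$total_low, rep$total_high)
#>  low  mid high
#>  1.2  1.9  2.7
```

The 143 surveyed colonies hold an estimated 728 529 breeding pairs
(5–95% CI 479 312–986 354), about 1.9% (1.2–2.7%) of the 37–40 million
world population.

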