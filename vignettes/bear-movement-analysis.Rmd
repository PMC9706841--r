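---
title: "Movement and habitat selection across life stages: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement and habitat selection across life stages: models and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bearmove)
```

`bearmove` analyzes hourly GPS telemetry of a large carnivore in a managed
boreal landscape at two spatial scales: habitat selection relative to the
whole study area (landscape scale, resource selection functions) and relative
to what an animal can reach within one hour (local scale, integrated step
selection analysis), with a second inferential stage that averages bear-year
models into population-level effects for two life stages, residents and
dispersers. This vignette documents the models, the tunable parameters and
their defaults, the synthetic data generator, and the numerical and design
choices a maintainer should know about.

## Telemetry cleaning

Raw fixes are resampled to an hourly grid anchored at minute zero, keeping at
most the nearest fix within ±180 s of each grid time. The grid anchor is a
design choice: the cleaning rule is "hourly ± 3 min" without a stated anchor,
and anchoring at :00 makes resampling deterministic and order-independent.
Fixes with dilution of precision (DOP) ≥ 10 are removed (strictly "less than
10" is retained, so DOP = 10.0 is dropped); missing DOP is retained with a
warning by default. Fixes whose raster cell is water are removed before bed
detection, because beds are defined on the retained series.

Bed sites (day and night resting clusters) are runs of at least 5 consecutive
fixes (≥ 4 h in one place at hourly sampling) in which each fix is within
30 m of the previous fix and within 50 m of every fix already in the run.
The scan is greedy and left-to-right, runs are maximal and non-overlapping,
and scanning resumes after an emitted run. Overlap handling is unspecified in
the underlying cleaning rule; the greedy maximal reading is the package's
choice and is locked in by an exhaustive contiguous-window oracle in the
tests. Bed-site fixes are flagged, and both selection analyses drop them.

The active period runs 25 April–20 August (118 days inclusive, the
denominator of the day-coverage rule). Resident bear-years need fixes on at
least 70% of those days; dispersers are clipped to their dispersal window and
may keep at most 6 calendar days outside the active period (extra days are
trimmed from the window edges proportionally).

## Dispersal segmentation

Step lengths are modeled with state-dependent gamma distributions and turning
angles with von Mises distributions in a hidden Markov model. The candidate
set holds seven specifications — one 1-state model and 2- and 3-state models
with three initializations each, spaced by step-length quantiles — fitted by
direct numerical maximization (BFGS) of the scaled forward-algorithm
likelihood on working parameters (log shapes, scales and concentrations,
transformed angle means, multinomial-logit transition rows). The initial
state distribution is the stationary distribution of the transition matrix.
The minimum-AIC converged fit wins; exact ties go to fewer states.
Numerical notes:

* zero step lengths are replaced by half the minimum positive length before
  density evaluation (the gamma density is degenerate at zero for shape > 1);
* turning angles are undefined for the first step after any gap and
  contribute no angular density there;
* the forward recursion runs in C++ for speed, and both the likelihood and
  the Viterbi decoder are verified against exhaustive path enumeration on
  short tracks (≤ 12 steps, relative tolerance 1e-8).

The dispersal window is delineated from the decoded states: runs of the
transit state (the state with the largest mean step length) separated by gaps
of at most 48 h are merged, and the longest merged run of at least 7 days
becomes the single dispersal window. The 7-day minimum and 48-h gap are
package defaults chosen against observed dispersal durations of roughly three
weeks to two months; both are configurable, and a no-dispersal result is
returned when no run qualifies.

## Covariates

All covariates live on a 25-m metric grid: bog and clearcut presence, terrain
ruggedness (Riley TRI: the root of summed squared elevation differences over
the 3×3 neighborhood, edge cells using available neighbors), and Euclidean
distances to water, forestry roads, public roads and buildings, computed
cell-center to cell-center (feature cells are zero; an empty feature layer
yields a sentinel equal to the extent diagonal, with a warning). Distances
are log-transformed as ln(d + 1); the 1-m offset is a package choice (roads
have d = 0 cells, and 1 m is negligible at study-area scales). Clearcuts
count from first cutting up to 10 years, inclusive, with one layer per
calendar year.

Habitat covariates are standardized as (x − mean)/sd. The reference sample is
the union of used and available records entering each model set, computed
once per life stage and scale; the (mean, sd) table is stored with every fit
so any result can be mapped back to natural units exactly (round-trip
verified to 1e-9). Whether standardization should be within bear-year or
study-wide is genuinely open; the stored table makes either reproducible.

## The two selection analyses

**Landscape scale (RSF).** Availability is the 100% minimum convex polygon of
all bear-years' fixes buffered by 18 km (the radius of a circular mean male
home range). Each bear-year gets 20 available points per used fix, sampled
uniformly within the buffered hull intersected with the raster extent and
excluding water cells (mirroring the used-fix water filter; the exclusion is
a package choice). Available points are drawn once per bear-year and shared
across that bear-year's candidate models so AICs are comparable. The
exponential RSF is fitted as used-vs-available logistic regression via
`stats::glm`.

**Local scale (iSSA).** Steps join consecutive non-bed fixes exactly 1 h
apart; a stratum requires a turning angle, i.e. two valid consecutive steps,
so the first usable stratum of each contiguous segment is the second step. A
single tentative gamma is fitted by maximum likelihood to the pooled used
step lengths of both life stages. Each used step is matched with 20 available
steps: lengths from the tentative gamma, turning angles uniform on (−π, π]
around the previous heading; endpoints outside the raster are redrawn (up to
100 rounds) rather than truncated, so the availability kernel is conditioned
on the landscape. The conditional logistic likelihood is maximized by
Newton–Raphson with step halving; standard errors come from the inverse
observed information, and the design is pre-checked for rank deficiency by
within-stratum centering (the conditional likelihood cannot identify a
stratum-constant covariate). Internally columns are rescaled to unit spread
for conditioning — SL in meters and cos TA differ by orders of magnitude —
and estimates are transformed back, leaving the returned scale untouched.

SL and ln SL enter in natural units while habitat covariates are
standardized. Standardizing the movement terms would break the gamma-update
algebra below, so the package deliberately keeps them natural; this is the
one place it deviates from standardizing every covariate, and the scale
choice is recorded with the fit.

The candidate table holds eight structures per scale: a core model (clearcut,
bog, TRI, distance to water — the prevalent habitat classes) extended by
forestry-road, public-road and building blocks singly, pairwise, and in full.
At the local scale each block adds the end-point distance term and its
ln SL × start-distance interaction.

## Population-level inference

Within each bear-year, candidate models are ranked by AIC and ΔAIC from that
bear-year's best model; each model's mean ΔAIC across bear-years and its
minimum-AIC tally summarize the set. The life-stage best model is the lowest
mean ΔAIC, which can exceed zero since no structure need win everywhere.

Bear-year coefficients are averaged by inverse-variance-weighted linear
regression of the coefficient on the centered mean availability of the
covariate (computed from that bear-year's available records — a package
reading, since "mean availability" admits several definitions), with weights
1/variance. The intercept is the population estimate at mean availability;
the availability slope is kept as a functional-response check. CIs use
estimate ± 1.96 × SE; a t-multiplier is a one-line switch (`ci_mult`), and
measured coverage with the normal multiplier is about 93% at 20–25
bear-years, which the recovery tests quantify. Effects whose CI covers zero
are "indifferent"; otherwise the label depends on covariate kind (for
distance covariates a positive coefficient means avoidance of the feature;
for ln SL × distance interactions a negative coefficient means faster
movement closer). A per-coefficient direction proportion reports how many
bear-years share the population sign; exact-zero coefficients count as
non-matching, and a zero population estimate leaves the proportion undefined.

## Movement rates and relative selection strength

The fitted SL/ln SL coefficients modify the tentative gamma:
shape′ = shape + β_lnSL + Σ_j β_lnSL:xj · xj(start), and
scale′ = 1/(1/scale − β_SL); the expected movement rate is shape′ × scale′
m/h. Rate curves sweep one focal distance covariate over 0–500 m in 25-m
increments (configurable) with other interacting covariates held at the mean
observed used-step start values, per bear-year, then averaged unweighted
across bear-years. Non-positive adjusted shapes or rates are errors at the
single-kernel level and exclusions (with a warning) at the curve level.

ln RSS(x₁, x₂) = Σ_j β_j (h_j(x₁) − h_j(x₂)) uses the population-averaged
estimates. For distance covariates the curve compares ending one mean step
length closer (floored at zero — the floor is a package choice) with staying
at the current distance, applying log-then-standardize to both; other
covariates are compared against the covariate mean. RSS(x, x) = 1 and
reciprocity RSS(x₁, x₂)·RSS(x₂, x₁) = 1 hold by construction and are asserted
in tests.

## The synthetic data generator

Landscapes are built from thresholded smooth Gaussian random fields (bogs,
lakes; ~200 m patch scale at 25-m resolution), rectangular harvest stands
with first-cut years (clearcuts aged out after 10 years), a forestry-road
network drawn as a minimum spanning tree over random seed points topped up to
a target density of 1.27 km/km², a few long straight public roads totalling
0.18 km/km², clustered buildings (12 clusters, ~8 buildings each, 150-m
scatter), and a smooth DEM (2-km correlation length, 40-m sd) from which TRI
is computed. These densities and the 25-m grid reproduce the covariate
contrast of a managed boreal study system; the generator makes no attempt to
mimic real geography, den sites, or seasonality beyond the active-period
window.

Trajectories are drawn from an explicit step-selection kernel: at each step,
200 candidate endpoints (configurable; large enough that the discrete choice
approximates the continuous kernel) get lengths from the tentative gamma and
turning angles from a von Mises around the previous heading, and one is
chosen with probability ∝ exp(β·covariates). Simulation uses von Mises
turning angles for realistic persistence even though fitting generates
available steps with uniform angles — the fitted model's cos TA term absorbs
the persistence, and the fitted structure remains the analysis model. Truth
coefficients are defined on landscape-wide standardized covariates; recovery
tests pass that same table to the fit so both sides share one scale, while
the pipeline default remains sample-based standardization. The default
resident and disperser kernels encode the qualitative pattern of interest —
bog/clearcut avoidance, building avoidance (selection for larger building
distances), faster movement nearer roads — with dispersers taking longer
(mean 730 m vs 586 m) and more directional steps.

Artifact injection adds what field data have and clean simulations lack:
resting clusters (runs of fixes collapsed onto a jittered center, clamped to
the track's bounding box), a stated fraction of DOP values above 10, and
deleted fixes creating gaps; the injection log is the oracle for the
cleaning filters. What the generator does not emulate — temporal covariate
dynamics, fix-rate heterogeneity, spatial autocorrelation of selection
beyond the kernel, den entry/exit — bounds what passing tests show about
real data: they validate the estimators and the pipeline logic, not the
ecology of any particular system.

## Study sizes and determinism

The shipped study configuration is 20 resident-like bear-years of 118 days
and 15 disperser-like bear-years of 43 days (the mean observed dispersal
duration) at hourly fixes on a 20 × 20 km landscape; recovery checks use 50
replicates of 3000+ strata (iSSA), 50 replicates of a 200:4000
used:available tilt (RSF), two-state chains of 3000 steps (HMM), and 500
replicates of the cheap IVW stage, sizes chosen so a full verification run
completes comfortably on one core. Every stochastic stage takes an explicit
seed; the pipeline derives per-stage, per-animal seeds (kept below 2^31)
from one master seed so stages can be rerun independently, and identical
configuration plus seed yields byte-identical outputs.

## Known limitations

* One projected metric CRS is assumed throughout; there is no reprojection.
* Step duration is fixed at 1 h by construction; no heterogeneous-interval
  steps.
* The second stage is fixed-effects IVW regression, not a random-effects
  meta-analysis.
* Gradual multi-year dispersal is out of scope for the segmentation module.
* Rate curves carry no uncertainty bands; they are means across bear-years.
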