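# bearmove

Movement and habitat selection of GPS-collared large carnivores across life
stages, analyzed at two spatial scales. `bearmove` implements the complete
workflow used to ask how human infrastructure (forestry roads, public roads,
buildings) shapes the movement and habitat selection of resident versus
dispersing male brown bears:

* **Telemetry cleaning** — hourly resampling (±3 min), a strict DOP < 10
  filter, removal of fixes over water, detection and removal of bed sites
  (clusters of ≥ 5 consecutive fixes with ≤ 30 m consecutive and ≤ 50 m
  pairwise spacing), and an active-period / day-coverage rule
  (25 April – 20 August, ≥ 70% of days for residents).
* **Dispersal segmentation** — hidden Markov models on step lengths (gamma)
  and turning angles (von Mises), seven candidate specifications selected by
  AIC, Viterbi decoding, and delineation of a single dispersal window from
  runs of the transit state.
* **Landscape-scale RSF** — exponential resource selection function: used
  fixes vs. 20:1 available points drawn from the buffered (18 km) minimum
  convex polygon of all fixes, fitted by logistic regression per bear-year.
* **Local-scale iSSA** — integrated step selection analysis: each used step
  is matched with 20 available steps (lengths from a pooled maximum-likelihood
  tentative gamma, turning angles uniform), and the conditional logistic
  likelihood

  ℓ(β) = Σ_strata [ η_used − ln Σ_j exp(η_j) ]

  is maximized by Newton–Raphson, with end-point habitat terms, SL, ln SL,
  cos TA, and ln SL × start-covariate interactions.
* **Candidate models** — eight structures per scale (core habitat model plus
  forestry-road / public-road / building blocks, singly, pairwise, and full),
  compared within bear-years by ΔAIC and summarized by mean ΔAIC and
  minimum-AIC tallies.
* **Population inference** — inverse-variance-weighted linear models of
  bear-year coefficients on centered mean availability (functional-response
  control); 95% CIs classify effects as selected / avoided / indifferent (or
  faster / slower), with the proportion of bear-years matching the population
  sign.
* **Post-estimation** — movement rates from the adjusted gamma kernel
  (shape′ = shape + β_lnSL + Σ β_lnSL:x · x, scale′ = 1/(1/scale − β_SL),
  rate = shape′ × scale′ m/h) and relative selection strength,
  ln RSS(x₁, x₂) = Σ β_j (h_j(x₁) − h_j(x₂)).

Because bear telemetry of this kind is not public, the package ships a
first-class synthetic module: landscapes with the covariate structure of a
managed boreal forest (thresholded Gaussian random fields for bogs, lakes and
clearcut stands; a ~1.3 km/km² forestry-road spanning network; ~0.18 km/km²
straight public roads; clustered buildings; a smooth DEM with 3×3 Riley TRI),
and trajectories drawn from a known step-selection kernel, so that every stage
is testable against ground truth.

## Worked example

One simulated resident bear-year, cleaned and fitted at the local scale:

```r
library(bearmove)

stack <- generate_landscape(landscape_config(extent_m = 10000, seed = 42))
stack
#> <landscape_stack> 400 x 400 cells at 25 m (10 x 10 km)
#>   bog 0.074, clearcut 0.059, water 0.040 of area; roads 1.28 / 0.22 km/km2 (forestry/public)

sim   <- simulate_issa_track(stack, default_truth("resident"), n_steps = 1500, seed = 7)
raw   <- inject_artifacts(sim$track,
                          bed_cluster_spec = list(n_clusters = 20, n_fixes = 6, radius_m = 10),
                          dop_spec = list(frac_high = 0.03), seed = 8)$track
clean <- preprocess_track(raw, stack = stack, life_stage = "resident",
                          min_day_coverage = 0.5)

steps  <- build_steps(clean)
kernel <- fit_tentative_gamma(steps$sl)
kernel
#> <gamma_kernel> shape 1.9650, scale 261.12 m (mean 513.1 m/h)

ss  <- generate_available_steps(steps, kernel, seed = 9, stack = stack)
sc  <- step_covariates(ss, stack)
fit <- fit_clogit(sc$data, candidate_models("issa")$forestry_roads,
                  model_name = "forestry_roads", bear_year_id = "demo_2015")
fit
#> <issa_clogit> demo_2015 / forestry_roads: 1168 strata (24528 rows), logLik -3391.30, AIC 6802.61
#>             sl log_sl cos_ta clearcut_end bog_end tri_end log_dist_water_end
#> estimate 1e-04 0.1182 0.5171      -0.3448 -0.5227  0.0821             0.2786
#> se       2e-04 0.0829 0.0451       0.0602  0.0765  0.0540             0.0588
#>          log_sl:clearcut_start log_dist_forestry_end log_sl:log_dist_forestry_start
#> estimate                0.1121               -0.0406                        -0.1368
#> se                      0.0951                0.0312                         0.0409
```

The bear avoids bogs and clearcuts at step end points (negative
coefficients), selects end points closer to forestry roads, and the negative
ln SL × distance-to-forestry-road interaction means it takes longer steps
when it starts near a road. Translating that into movement rates with the
adjusted gamma kernel:

```r
sv <- function(d) c(clearcut_start = std_value(0, "clearcut", sc$std),
                    log_dist_forestry_start = std_value(log(d + 1), "log_dist_forestry", sc$std))
a0   <- adjust_gamma(kernel, coef(fit), sv(0))
a500 <- adjust_gamma(kernel, coef(fit), sv(500))
round(c(on_road = a0$shape * a0$scale, at_500m = a500$shape * a500$scale))
#> on_road at_500m
#>     695     516
```

i.e. this bear-year moves ~180 m/h faster when a step starts on a forestry
road than 500 m away from one.

The multi-animal study — 20 resident-like and 15 disperser-like bear-years on
a 20 × 20 km landscape, both scales, model selection, population estimates and
rate/RSS curves — runs end-to-end with:

```r
res <- run_pipeline(pipeline_config(seed = 1, out_dir = "out"))
```

## Package layout

* `R/landscape.R`, `R/covariates.R` — synthetic landscapes, TRI, distance
  transforms, extraction, standardization
* `R/simulate.R`, `R/vonmises.R` — step-selection and HMM trajectory
  simulators, artifact injection
* `R/preprocess.R` — resampling, DOP/water filters, bed sites, active period
* `R/hmm.R`, `src/forward.cpp` — HMM fitting, AIC selection, Viterbi,
  dispersal delineation
* `R/rsf.R`, `R/issa.R`, `R/models.R` — the two selection analyses and the
  candidate-model table
* `R/population.R`, `R/postestimation.R` — IVW second stage, movement rates,
  RSS
* `R/pipeline.R` — configuration and the end-to-end driver
* `vignettes/bear-movement-analysis.Rmd` — methods and design notes
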