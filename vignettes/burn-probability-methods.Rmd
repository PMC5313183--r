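---
title: "Methods: stochastic burn probability and factor contribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stochastic burn probability and factor contribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(firebp)
```

firebp analyses fire regimes in which most ignitions are human-caused and
fires are small and frequent — the situation typical of intensively used
subtropical coniferous forest in East and South China. The analysis has
three linked stages (occurrence, size, burn probability), each a classed
model object, followed by a variance decomposition that asks which factor
group — fuel, topography or human activity — explains the spatial pattern
of fire likelihood.

## 1. Ignition occurrence

Occurrence is modelled as a binary logistic regression contrasting
observed ignition points (weather of the ignition day attached) with an
equal number of pseudo-absence points. Pseudo-absences are drawn
uniformly over burnable cells but excluded from a disc of radius equal to
the ignitions' mean nearest-neighbour distance around every ignition
(`mean_nn_distance()`, `sample_nonignitions()`): points that close to an
observed fire are not credible absences at the scale the data resolve.
Each pseudo-absence receives a uniformly random archive day as its
"non-ignition day", mirroring how the ignition day is attached to a
presence row; the model therefore sees the same weather covariates on
both labels.

Before fitting, candidate covariates are screened pairwise: whenever two
covariates have |Pearson r| > 0.4, the one with the weaker absolute
point-biserial association with the label is dropped
(`screen_collinearity()`). The threshold is the conventional moderate-
correlation cut-off for this screen; perfectly collinear duplicates are
dropped regardless of threshold, and the "others" fuel proportion is
removed a priori as the simplex baseline. The fit itself is IRLS
(`stats::glm`) run to a convergence epsilon of 1e-10 with at most 100
iterations; a maximum-likelihood coefficient exceeding 15 in absolute
value is treated as (quasi-)separation and raised as an error rather than
reported, since on these covariate scales no plausible odds ratio is that
extreme. Reported per-variable quantities are the coefficient B, its
standard error, the Wald chi-square (B/SE)^2 with its p-value, and the
odds ratio exp(B). Fit quality is summarised by Cox & Snell
R^2 = 1 − exp(2(L0 − L1)/n), its Nagelkerke rescaling, and ROC-AUC
computed as the Mann–Whitney pairwise-win probability with ties counted
half.

`ignition_surface()` turns a fit plus one day's weather into a per-cell
probability surface (inverse logit of the linear predictor, non-burnable
cells zeroed). Because the landscape part of the predictor is static, the
simulator caches it and pays one vectorised inverse-logit per fire day.

## 2. Fire size

Fire size is strongly non-linear in its drivers, so it is modelled by an
ensemble of ten random forests (`fit_size_ensemble()`, on
`randomForest`), each trained on an independent random 2/3 subsample of
the catalogue with the remaining third held out; ntree = 1000 per forest
(large enough for error convergence at a few hundred observations) and
mtry tunable by an out-of-bag sweep starting from the regression default
floor(p/3) (`tune_mtry()`, ties to the smaller value). Averaging ten
forests damps the subsample-to-subsample variability of both prediction
and importance. Three design points deserve note:

* "Out-of-bag" here means the held-out third of each member model, not
  per-tree bagging OOB — the ensemble protocol fixes an explicit
  train/holdout split per member, and variance explained is
  1 − MSE_holdout/Var(y_holdout) averaged over members.
* Holdout residuals (observed − predicted, ha) are pooled across all ten
  members into one residual pool. `draw_stochastic_size()` returns the
  ensemble prediction plus one bootstrap draw from that pool, floored at
  0.3 ha (the smallest observable fire). Draws below the floor are
  clamped rather than redrawn by default, which biases the mean up very
  slightly; `redraw = TRUE` is available where that matters.
* Importance is permutation %IncMSE averaged over members and reported
  descending; it is a z-like score, so planted-signal recovery rather
  than its absolute magnitude is what the tests pin down.

## 3. Burn probability

`run_simulation()` repeats a synthetic fire year `n_runs` times. Within
each run: monthly ignition counts are Poisson with the historical monthly
means; each ignition day is uniform within its month; its weather is a
uniform draw from all archive days whose day-of-year lies within ±10 days
(circularly across New Year) — 21 × 20 = 420 candidates for a 20-year
archive; its location is drawn from that day's ignition surface by
acceptance–rejection with the surface maximum as envelope; and its target
size is a stochastic draw from the size model.

Spread follows R = R0·Kf·Kw·Kt with R0 = aT + bv + c(1−h) − d (T the
day's maximum temperature in °C, v wind speed in m/s, h relative humidity
as a fraction — the archive stores percent and the model converts), and
multipliers Kw = exp(0.1783 v), Kt = exp(3.533 tan(φ)^1.2), Kf ∈ [0.8,
1.8] by fuel type. Defaults follow the coefficients calibrated on Chinese
forest-fire observations (a = 0.03, b = 0.05, c = 0.01, d = 0.3); Kf
defaults order pine (1.2) > fir (1.0) > others (0.9) > broadleaf (0.8),
inside the calibrated band and in the flammability order of these
systems. A negative R0 clamps to zero: no spread.

The cellular automaton is arrival-time propagation on the 8-neighbour
grid: the crossing time from cell i to neighbour j is the centre distance
(cell size, ×√2 on diagonals) divided by the mean of the two cells' base
rates, and cells ignite in arrival-time order via a discrete-event
(Dijkstra) queue. This formulation was chosen over rule-based synchronous
automata because it is sweep-order-independent and checkable against an
independent shortest-path oracle, which the test suite does on random
landscapes. The slope multiplier has no printed downslope branch, so by
default Kt applies per directed edge with φ = the upslope angle from the
elevation difference (flat/downslope edges get Kt = 1); the
`isotropic_slope` flag instead folds each cell's scalar slope into its
own rate, the simpler literal reading. Wind direction is carried in the
weather but unused: the rate model depends on speed only, so spread is
isotropic in wind. A fire is one event on one day with one weather draw
(no multi-day burning; termination is purely size-based), and same-year
fires may reburn cells — counts accumulate per event. Cells with rate 0
(or outside the burnable mask) are impassable barriers; a fire whose
target exceeds what barriers allow simply stops. Because cells accrete
one at a time, the realized raster footprint overshoots the drawn target
by less than one cell.

The catalogue records both the drawn (continuous) size and the raster
footprint. The continuous size is the "observed" size of an event — real
fire registries record sizes far below one 200-m cell (4 ha), and the
generator's target moments and the ECDF comparison of historical vs
simulated sizes (`ks_two_sample()`, asymptotic two-sample
Kolmogorov–Smirnov) are defined on it; the footprint is what accumulates
into burn counts. BP per cell is burn count / n_runs.

## 4. Factor contribution

`bp_importance()` regresses log BP on seven layers — pine, fir and
broadleaf proportions, stand age (fuel); slope and elevation
(topography); distance to nearest road (human; settlement distance is
excluded as collinear with it) — and decomposes the R^2 by lmg: each
variable's share is the average over all p! orderings of its sequential
R^2 increase. The implementation is exact, computing R^2 for all 2^p
covariate subsets from the correlation structure and combining gains with
the Shapley weights |S|!(p−|S|−1)!/p!, identical to ordering enumeration
but exponentially cheaper; a sampled-permutation mode covers larger p.
Singular submodels fall back to a pseudoinverse R^2 and are flagged.
Group shares are sums of member shares; shares are invariant to the log
base and to linear rescaling of covariates.

Cells that never burned have undefined log BP. By default they are kept
with BP floored at half the detection limit, 1/(2·n_runs), the standard
convention for values censored at a detection threshold. The alternative
(excluding them) is available but conditions the sample on the response:
it removes exactly the remote, rarely-burned end of the access gradient
and thereby attenuates large-scale contributions relative to fragmented
local ones.

## 5. The synthetic world

Real forest-survey and fire-registry data of this kind are not
redistributable, so the package generates worlds with the statistical
structure the analysis assumes, with known truth for recovery tests
(`synth_config()`, `synth_landscape()`, `gen_weather()`,
`gen_fire_history()`).

* **Terrain** — a smooth field rising from one meandering valley plus
  low-amplitude spectral roughness; slope/aspect by central differences.
  Relief 1200 m over a 20 × 20 km grid at 200-m cells emulates a
  mid-subtropical mountain county (valley floor ~170 m).
* **Fuel** — Voronoi patches (mean 25 cells ≈ 1 km², standing in for
  survey subcompartments) with Dirichlet-drawn proportions of
  pine/fir/broadleaf/others (mean shares ≈ 14/39/18/29%, concentration
  1.2 so patches are strongly dominated by one type); the pine
  concentration decays with patch elevation above 700 m, the upper range
  of the dominant low-elevation pines. Stand age is gamma with mean 17.9
  and sd 13.7 years.
* **Human activity** — a trunk road along the valley, settlements placed
  preferring low elevation and clustering within ~4 km of a town centre,
  branch roads connecting each settlement to the trunk; distances are
  exact Euclidean km, population density a sum of exponential settlement
  kernels. This is the access gradient: generative log-odds fall by
  0.45/km of settlement distance and 0.30/km of road distance, which
  makes access the dominant *spatial* ignition driver, while the fuel
  proportions keep the largest *per-unit* coefficients (pine 2.5 per
  unit proportion) — so odds ratios rank fuel first even though the
  access field carries more spatial variance.
* **Weather** — grid-constant days (the emulated region is too small for
  useful spatial weather gradients): seasonal sinusoid + AR(1) mean
  temperature (16.9 ± ~7 °C), maximum offset above it, humidity
  anti-correlated with the temperature anomaly and boosted on rain days,
  Bernoulli–Gamma precipitation putting ~80% of ~1700 mm/yr in
  March–September, lognormal wind maxima (≈1.15 m/s mean), uniform
  16-sector directions. The calendar uses 365-day years (no Feb 29), so
  weather-window counts are exact.
* **Fire history** — generated by the same simulator machinery with the
  true ignition coefficients and a lognormal ground-truth size model
  (log-size linear in pine proportion, log(1+population density) and
  slope; sd 0.7; truncated to 0.3–80.3 ha; intercept set so world mean
  size ≈ 5.4 ha). Monthly ignition rates sum to 11.25/yr with ~85% in
  December–May. Historical events use their own date's archive weather
  rather than a window draw. About 1 fire in 225 is labelled lightning,
  ~28% unknown, the rest human — labels only; all ignitions share one
  surface.

What the generator does **not** emulate: spatial autocorrelation of
weather, multi-day fires, fuel succession or post-fire fuel change
(layers are static across runs), anisotropic wind-driven spread,
suppression effort beyond the size-termination rule, and registry
artefacts such as location rounding or missed small fires. Passing
recovery tests therefore show the pipeline recovers the structure this
world has, not that real data meet these assumptions.

## 6. Problem sizes and numerical choices

The shipped tests fit on a shared 60 × 60, 10-year world; the
parameter-recovery suite runs ten independent 100 × 100, 20-year worlds
with 1000-replicate simulations (the scale at which ~2 expected burns
per cell make the spatial signal resolvable; a trial at 60 × 60 with 400
runs drowned it in Poisson noise); the acceptance script runs one such
world end to end. Size-termination self-consistency is checked at 50-m
cells, where the sub-cell overshoot is small against the size
distribution — at 200-m cells the 4-ha quantisation dominates and the
realized-vs-target ECDF comparison is not meaningful. Other numerical
choices: Dijkstra ties (measure-zero under continuous rates) resolve by
queue order; the acceptance–rejection sampler proposes in batches with
the exact envelope, so it is unbiased at any acceptance rate; subset R^2
uses the correlation matrix with a pseudoinverse fallback; Shapley
weights are computed in log-factorial space.

## 7. Limitations

The lmg decomposition attributes shared variance between collinear
groups (road distance and elevation both follow the valley) by
averaging, not by causal assignment; the ceteris-paribus OLS coefficients
carry the same caveat. BP estimates at 1000 runs retain visible Poisson
noise, which deflates all R^2-based quantities relative to a 10^4-run
simulation. The logistic surface is used as a relative ignition density;
its intercept is not calibrated to absolute daily rates (counts come from
the monthly Poisson model). The spread model is an empirical surface-fire
formula: no crowning, spotting or fuel-moisture dynamics.
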