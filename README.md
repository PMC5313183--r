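# firebp

Stochastic burn-probability simulation and factor-contribution analysis
for human-dominated fire regimes.

In intensively used subtropical forest — fragmented fuel mosaics, valley
roads and settlements, frequent small human-caused fires — fire managers
increasingly work with **burn probability (BP)**: the chance that a given
cell burns in a year, estimated by simulating very many fire years. The
question this package addresses is which factor group — fuel composition,
topography, or human activity — explains fire *occurrence*, fire *size*,
and BP, and whether those answers differ. Because BP compounds repeated
ignition and spread, a factor's influence can be amplified or attenuated
between the single-event models and the BP map.

The pipeline has three modelling stages plus a decomposition:

1. **Ignition occurrence** — binary logistic regression of ignition
   points against pseudo-absences sampled outside the ignitions' mean
   nearest-neighbour distance; covariates screened at |r| > 0.4;
   reported per variable as B, SE, Wald = (B/SE)², p, and odds ratio
   exp(B), with Cox & Snell R² = 1 − exp(2(L0 − L1)/n), Nagelkerke R²,
   and ROC-AUC (Mann–Whitney form).
2. **Fire size** — an ensemble of 10 random forests (ntree = 1000,
   tunable mtry), each on a random 2/3 subsample; averaged permutation
   importance (%IncMSE); stochastic size = prediction + a bootstrap draw
   from the pooled holdout residuals.
3. **Burn probability** — replicate fire years: Poisson monthly ignition
   counts, uniform dates, weather drawn from a ±10-day archive window,
   locations by acceptance–rejection on the day's ignition surface, and
   cellular-automaton spread at rate **R = R₀·K_f·K_w·K_t** with
   R₀ = aT + bv + c(1 − h) − d, K_w = exp(0.1783 v),
   K_t = exp(3.533 tan(φ)^1.2), until the drawn target size is reached.
   BP = per-cell burn count / runs.
4. **Factor contribution** — OLS of log BP on fuel, topography and
   human-activity layers, with R² decomposed into exact **lmg (Shapley)**
   shares per variable and group.

A synthetic-world generator (terrain, fuel mosaic, valley road and
settlement system, 20-year daily weather, model-generated fire history
with known true parameters) makes every stage testable without
restricted survey data. See the methods vignette
(`vignettes/burn-probability-methods.Rmd`) for model details, defaults
and limitations.

## Worked example

```r
library(firebp)
cfg  <- synth_config(seed = 42)          # 100 x 100 cells, 20-year archive
pipe <- run_all(cfg, n_runs = 1000, sim_seed = 42)
print(pipe)
```

Output (~1 minute on one CPU; abridged):

```
== Fire-regime analysis pipeline ==
fire_landscape: 100 x 100 cells @ 200 m (400.0 km^2)
  elevation 195-1417 m; fuel classes: fir > others > broadleaf > pine
  8 settlements, 140 road cells
history: 207 fires over 20 years (mean size 5.43 ha)

-- ignition occurrence --
Binary logistic ignition-occurrence model
        variable      B    SE   Wald   Sig    ExpB
     (Intercept)  4.919 1.419 12.022 0.001 136.807
       prop_pine  2.438 0.589 17.137 0.000  11.453
  prop_broadleaf -3.421 0.785 18.984 0.000   0.033
    dominant_age -0.027 0.012  4.920 0.027   0.973
           t_avg -0.049 0.023  4.765 0.029   0.952
 dist_settlement -0.736 0.083 77.857 0.000   0.479
n = 414; Cox & Snell R2 = 0.491; Nagelkerke R2 = 0.654; AUC = 92.20%

-- fire size --
Fire-size ensemble: 10 random forests (ntree = 1000, mtry = 4)
  trained on 207 fires (67% subsamples); variance explained = 35.50%
  top importance (Avg %IncMSE):
    prop_pine           24.2769
    prop_fir            12.8098
    pop_density         11.7974

-- burn probability --
Burn-probability simulation: 11271 fires over 1000 replicate years
  BP: mean 0.00179, median 0.00100, max 0.02800; burned cells: 5598

-- factor contribution --
Factor contribution to burn probability (10000 cells, R2 = 0.403)
Group shares of R2:
      group share
      human 0.147
       fuel 0.139
 topography 0.117

validation: KS D = 0.109 (p = 0.016); annual burned area 56.2 ha (hist)
vs 40.4 ha (sim); 11.27 fires/run (expected 11.25)
```

Reading the numbers: the occurrence model ranks **fuel first by odds
ratio** (pine proportion, exp(B) ≈ 11.5 per unit proportion, against
0.48 per km of settlement distance) and the size ensemble ranks pine
proportion first by %IncMSE — yet the BP decomposition puts the **human
group first** (0.147 vs fuel 0.139): overlapping repeated ignition and
spread along the access gradient amplifies human influence relative to
the fragmented fuel mosaic. That reversal is the pipeline's headline
behaviour, and the test suite checks it across ten independent worlds.
Screened-out covariates (here elevation, road distance, population
density — collinear with the retained access and fuel variables) are
listed in `summary(pipe$ignition)`.

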