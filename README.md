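# spraytrack

Season-long assessment of adulticide spraying against the Asian tiger
mosquito *Aedes albopictus*, from sticky-trap surveillance and
caged-mosquito sentinel experiments.

Municipal mosquito control routinely sprays pyrethroid adulticides, but
deciding whether a *season* of repeated sprayings suppressed the
population is statistically delicate: single-treatment scores are noisy
(adults re-emerge within days) and treated/untreated comparisons are
confounded by site-specific micro-climate. `spraytrack` implements the
full assessment chain for a two-site monitoring design:

* **Henderson–Tilton effectiveness** of single treatments, for caged and
  wild mosquitoes:
  `%E = 100 (1 − T_after·U_before / (T_before·U_after))`,
  negative values clamped to 0 for reporting.
* **Mixed models** (binomial and Poisson GLMMs via the Laplace
  approximation, Gaussian LMMs via REML; random intercepts with
  `date/line` nesting): mortality vs exposure/permethrin/sex, mortality
  vs distance from the spray line, water leftover vs weather, and trap
  counts vs water leftover × site.
* **Simulation-based validation**: 10,000 binomial draws at the
  model-predicted mortality per sentinel cage, observed deaths flagged
  against the exact-style 0.025/0.975 rejection bounds.
* **Divergence detection**: ARIMA pre-whitening of each site's
  per-collection mean series, Pearson correlation of residuals over
  expanding windows, and exact dynamic-programming change-point
  segmentation (BIC-selected) of the correlation sequence. A *drop* in
  the mosquito correlation with no concurrent drop in the water-leftover
  correlation attributes the divergence to treatment rather than
  climate.
* A **synthetic-data generator** reproducing the design (24 + 19 traps,
  36 twice-weekly collections, 7 cage experiments) so the whole chain is
  testable offline.

See `vignettes/spraytrack-methods.Rmd` for the models, parameter
defaults and known limitations.

## Worked example

```r
library(spraytrack)

henderson(20, 5, 10, 10)        # treated 20 -> 5, untreated stable
#>   raw_pct effectiveness_pct
#>        75                75

cfg   <- synthetic_config(seed = 2013)
cages <- simulate_cage_experiment(cfg)
caged_effectiveness(cages, "distance")
#>   distance_m effectiveness_pct ci_lower ci_upper n_treatments
#> 1         10             82.25    74.28    90.22            7
#> 2         30             47.09    37.47    56.72            7
#> 3         50             19.64     6.45    32.83            7
#> 4         70              2.68    -0.90     6.26            7
```

Effectiveness decays from ~82% at 10 m from the spray line to ~3% at
70 m — spraying only protects a narrow corridor. The distance model
quantifies the decay (≈ −0.08 logit units per metre):

```r
fit2 <- run_glmm2(cages)
#>          term estimate       se      z          p
#> 1 (Intercept)  2.50908 0.229184  10.95  6.802e-28
#> 2  distance_m -0.08191 0.002792 -29.34 3.037e-189

validate_cages(fit2, cages, seed = 1)[1:2, ]
#>   treatment_id cage_id n_initial observed_dead predicted_p q0.025 q0.975  flag
#> 1           T2    VC-1        40            19       0.809     26     38 under
#> 2           T3    VC-1        40            40       0.809     26     38  over
```

Sentinel-cage mortality is predicted at 81% at 13 m; observed deaths
outside the [26, 38] rejection band (here 19 and 40 of 40) flag
treatments whose real-world kill differed significantly from the model.

The headline analysis — did the *strategy* change the population
trajectory? — on a simulated season with strong suppression from
collection 15:

```r
cfg <- synthetic_config(treatment_effect = 0.05, seed = 1301)
mon <- simulate_monitoring(cfg)
divergence_report(mon$traps, default_schedule(), p_max = 1, q_max = 1)
#> Divergence analysis (expanding-window residual correlations)
#> - mosquito: 1 break(s) at collection 15; segment means: 0.39 -> -0.08
#> - water: 1 break(s) at collection 15; segment means: 0.91 -> 0.99
#> Mosquito break precedes/coincides with water break: TRUE
```

The inter-site mosquito correlation collapses (0.39 → −0.08) exactly at
the simulated divergence onset (collection 15), while the water-leftover
correlation — the eco-climatic control — stays high (0.91 → 0.99): the
divergence is attributable to treatment, not weather.

## Command line

```sh
exec/spraytrack run-all --config run.yaml --out results/
exec/spraytrack simulate|effectiveness|cage|field|divergence ...
```

`run.yaml` holds a `synthetic:` block (or `trap_file`/`cage_file`/
`weather_file` paths), the treatment schedule, and model options; see
`inst/extdata/example-run.yaml`.

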