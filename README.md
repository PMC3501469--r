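# smoltcjs

Spatial Cormack–Jolly–Seber (CJS) survival estimation for acoustic-tagged
juvenile salmonids (smolts) migrating seaward past fixed receiver lines.

## The problem

Steelhead smolts leaving their natal rivers carry surgically implanted
acoustic transmitters and are re-"encountered" when they swim past
cross-channel receiver lines — here a river-mouth line (RM), the Hood Canal
Bridge line (HCB), an Admiralty Inlet line (ADM) and a terminal Strait of
Juan de Fuca line (JDF). Each fish therefore yields a binary encounter
history over ordered occasions (release, RM, HCB, ADM, JDF), and the CJS
open-population model separates *apparent survival* φ<sub>s</sub> through
each migration segment from *detection probability* p<sub>k</sub> at each
line:

P(history) = ∏<sub>k≤l</sub> φ<sub>k</sub> p<sub>k</sub><sup>y<sub>k</sub></sup>(1−p<sub>k</sub>)<sup>1−y<sub>k</sub></sup> · χ<sub>l</sub>,  χ<sub>T</sub> = 1,  χ<sub>k</sub> = (1−φ<sub>k+1</sub>) + φ<sub>k+1</sub>(1−p<sub>k+1</sub>)χ<sub>k+1</sub>

where l is the last detection. Because nothing lies beyond the terminal
line, φ<sub>T</sub> and p<sub>T</sub> are confounded; the package fixes the
terminal p at an externally derived value (default 0.685, with 95% bounds
0.428/0.863 swept as a sensitivity analysis). Candidate φ/p models built
from a design-matrix grammar are ranked by QAICc,

QAICc = −2 ln L / ĉ + 2K + 2K(K+1)/(n<sub>eff</sub> − K − 1),

with the variance-inflation factor ĉ estimated from m-array contingency
goodness-of-fit tests. Segment survival converts to a distance-scaled
instantaneous mortality rate M = −ln φ / d (per km), and migration behavior
is summarized by travel rates, migration range, a Williams-corrected G-test
of smolt index versus estuary detection, and two-way fixed-effects models
with Tukey–Kramer comparisons.

A configurable simulator generates cohorts, true fates and detection-event
logs with exactly the statistical structure the estimator assumes, so every
stage of the pipeline is testable without field data.

## Worked example

Simulate one 500-fish release group, build histories, and fit a
segment-structured CJS model with the terminal detection probability fixed:

```r
library(smoltcjs)

cfg <- single_group_config("SkokomishW", 2008, 500,
                           phi = c(0.95, 0.88, 0.40, 0.45),
                           p_rm = 0.9, seed = 1)
sh  <- simulate_histories(cfg)
fit <- cjs_fit("phi ~ segment; p ~ segment; fix p[JDF]=0.685", sh$eh)
fit
#> CJS fit: phi ~ segment; p ~ segment; fix p[JDF]=0.685
#>   logLik -905.336  K 8  (estimated betas 7)  converged TRUE
#> survival (phi):
#>   segment estimate     se fixed
#> 1   PR-RM    0.945 0.0126 FALSE
#> 2  RM-HCB    0.840 0.0329 FALSE
#> 3 HCB-ADM    0.477 0.0517 FALSE
#> 4 ADM-JDF    0.316 0.0519 FALSE
#> detection (p):
#>   segment estimate     se fixed
#> 1      RM    0.925 0.0141 FALSE
#> 2     HCB    0.801 0.0330 FALSE
#> 3     ADM    0.707 0.0711 FALSE
#> 4     JDF    0.685     NA  TRUE
```

The per-segment estimates recover the generating values (0.95, 0.88, 0.40,
0.45) within sampling error. Cumulative marine survival (RM→JDF) with a
delta-method SE, goodness-of-fit, and QAICc:

```r
marine_survival(fit)
#>   marine_survival        se
#> 1       0.1267032 0.0189358

gof <- release_gof(build_marray(sh$eh))
gof
#> GOF: chi2 = 3.748 on 3 df;  c-hat = 1.249 (raw 1.249)

qaicc(fit$loglik, fit$K, n_eff = 500, c_hat = gof$c_hat)
#> [1] 1465.586
```

About 12.7% of fish that reached saltwater survive to the terminal line —
the product 0.840 × 0.477 × 0.316 of the marine segment estimates.

The full pipeline (simulate → histories → model set → GOF/ĉ → ranking →
survival/mortality/behavior reports) is driven by a JSON config:

```r
run_pipeline(run_config(system.file("extdata", "demo_config.json",
                                    package = "smoltcjs")))
```

which writes `model_table.csv`, `survival_estimates.csv`,
`marine_survival.csv`, `mortality_rates.csv`, behavior tables, a MARK-style
`histories.inp`, and a reproducibility manifest into the output directory.

## Layout

- `R/` — data types and IO (`fish_records`, `read_tables`, `write_inp`),
  simulator (`sim_config`, `simulate_dataset`, `simulate_histories`),
  encounter metrics (`build_encounter_histories`, `travel_rate`,
  `migration_range`, `density_table`), CJS engine (`parse_model_spec`,
  `build_design`, `cjs_negloglik`, `cjs_fit`, `profile_confounding`),
  selection (`build_marray`, `release_gof`, `qaicc`, `rank_models`),
  mortality (`cumulative_survival`, `instantaneous_mortality`,
  `sensitivity_range`, `mortality_rate_table`), behavior (`g_test_adj`,
  `two_way_anova`, `tukey_hsd`), pipeline (`run_config`, `run_pipeline`).
- `vignettes/smolt-survival-methods.Rmd` — the model, its assumptions, and
  every numerical/design choice.
- `tests/testthat/` — unit, property and acceptance suites.
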