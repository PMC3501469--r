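---
title: "Methods: spatial CJS survival for acoustic-tagged smolts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial CJS survival for acoustic-tagged smolts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smoltcjs)
```

## The model

A tagged smolt released in its natal river passes up to four receiver
lines on its way to the ocean: the river mouth (RM), the Hood Canal Bridge
(HCB), Admiralty Inlet (ADM) and the Strait of Juan de Fuca (JDF). The
data unit is a binary encounter history $y = (1, y_1, \dots, y_4)$ over
the release occasion and the four lines. The Cormack–Jolly–Seber model
assigns each fish a probability

$$P(y) \;=\; \prod_{k \le l} \varphi_k\, p_k^{y_k} (1-p_k)^{1-y_k}
\;\cdot\; \chi_l,$$

where $l$ is the last occasion with $y_l = 1$, $\varphi_k$ is apparent
survival through segment $k$ (PR–RM, RM–HCB, HCB–ADM, ADM–JDF), $p_k$ is
detection probability at line $k$, and the never-seen-again tail is the
recursion $\chi_T = 1$, $\chi_k = (1-\varphi_{k+1}) +
\varphi_{k+1}(1-p_{k+1})\chi_{k+1}$. "Apparent" matters: a fish that dies
and a fish that never migrates (a residual) are indistinguishable, so
$1-\varphi$ mixes both.

The likelihood implementation (`cjs_negloglik_real`) works directly on
per-fish real-scale parameter matrices and is verified, property-style,
against exhaustive enumeration of every death-segment/detection-outcome
combination for all $2^4$ histories across 1,000 random parameter draws
(agreement to $10^{-10}$).

### Design matrices and the model grammar

Models are written in the field's shorthand, e.g.

```
phi ~ segment * SkokH + rd; p ~ segment + RM:line; fix p[JDF]=0.685
```

Survival terms may use `segment`, the population-grouping factors
(`population`, `reartype`, `hatchery`, `SkokH`, `DuckH`), `year`, and the
standardized covariates `rd` (release day), `L` (fork length) and `K`
(condition factor). Detection terms use `segment` (the occasion line),
`RM:line` (river-mouth-specific detection at the RM occasion only — each
river's mouth line has its own efficiency while HCB/ADM/JDF are shared),
`year` and `rd`. Both parameters use the logit link (the standard choice
for this model family; the source analyses do not state theirs).

Rows of the design are (fish, segment) cells, fish-major; `*` expands to
main effects plus interaction through R's `model.matrix`. Aliased columns
are dropped deterministically left-to-right. Covariates are standardized
to mean 0, SD 1 before fitting, with the transform recorded; published
covariate coefficients are on an unknown scale, so no numeric agreement
is claimed for them.

### Parameter counting

The reported count $K$ is the number of non-aliased design columns built
over *all* cells, including those later pinned by `fix` clauses; the
fixed real value itself is never counted. Under this convention the
standard top model (`phi ~ segment * SkokH + rd; p ~ segment + RM:line`
with terminal p fixed) counts exactly 15 parameters, matching its
published count. The convention is not perfectly self-consistent in the
published table itself (two models differing by one covariate are printed
with equal $K$), so only the top model's count is asserted. Betas whose
columns act only on fixed cells are excluded from the optimization.

### The fixed terminal line

Beyond JDF there are no more receivers, so only the product
$\varphi_T\, p_T$ is identifiable — the likelihood is exactly flat along
the compensating ridge $\{(\varphi, c/\varphi)\}$, which
`profile_confounding()` demonstrates numerically. The package therefore
fixes $p_{JDF}$ (default 0.685, an external estimate from a comparable
receiver line), and `sensitivity_range()` re-fits with the 95% bounds
0.428 and 0.863. Cumulative marine survival is monotone decreasing in
the assumed terminal p: if the line detects better than assumed, the
missing fish must be dead.

### Fitting and standard errors

Maximization is quasi-Newton (BFGS) from $\beta = 0$ (real scale 0.5)
with up to three jittered restarts on non-convergence; the covariance is
the inverse numerical Hessian at the optimum; real-scale estimates and
delta-method SEs are evaluated at the standardized-covariate mean. When
$\hat c > 1$, real-scale SEs are inflated by $\sqrt{\hat c}$
(quasi-likelihood convention). Before optimization, fish with identical
design rows and histories are collapsed to weighted representatives —
an exact reparameterization that leaves the likelihood, estimates and
Hessian unchanged while making 10,000-fish fits essentially instant.
Cumulative marine survival SEs use the delta method on the log scale:
$\mathrm{d}\log \prod_s \varphi_s / \mathrm{d}\beta =
\sum_s (1-\varphi_s) x_s$.

## Goodness-of-fit and overdispersion

`release_gof()` pools contingency-table components testing the two CJS
assumptions, in the style of the classic RELEASE tests: among animals
seen again after occasion $k$, next-detection timing must not depend on
whether they were seen at $k$ (TEST2-type), and among animals seen at
$k$, being seen again must not depend on having been seen before
(TEST3-type). Cells are pooled (adjacent columns merged) until expected
counts reach 2; components sparser than that are dropped. Then
$\hat c = \chi^2_{\text{total}} / \mathrm{df}_{\text{total}}$, floored at
1 for downstream use. Calibration work uses the unfloored ratio, since
the floored mean is $\ge 1$ by construction: under exact CJS generation
the mean unfloored $\hat c$ over 100 replicates of 2,000 fish sits near 1.

A deliberate design choice concerns the overdispersion knob. Per-fish
frailty on logit($\varphi$) *alone* is undetectable here: with a single
release cohort, a survival mixture is observationally equivalent to a
time-dependent CJS with adjusted $\varphi_s$, and detections are
independent of the frailty given survival, so every GOF margin stays
independent. The simulator's `frailty_sd` therefore applies one shared
per-fish normal deviate to both logit($\varphi$) and logit($p$) — a
latent "fish quality" affecting vitality and detectability. Detection
heterogeneity is precisely what these contingency tests have power
against, and at SD 1.5 the unfloored $\hat c$ exceeds 1 in essentially
every replicate.

## Model selection

$\mathrm{QAICc} = -2\ln L/\hat c + 2K + 2K(K+1)/(n_{\mathrm{eff}}-K-1)$,
with Akaike weights $w_i = \exp(-\Delta_i/2) / \sum_j \exp(-\Delta_j/2)$
normalized over the candidate set. The effective sample size convention
is the number of released animals (302 in the default emulation);
capture–recapture software varies on this point and the choice is
configurable. Weights quoted for a subset of models do not renormalize to
full-set weights — asserted as a documented property.

## Distance-scaled mortality

Instantaneous mortality is expressed per kilometre rather than per day:
smolts cover similar corridor distances at variable speeds, so distance
is the natural exposure scale. Survival $\varphi$ over a segment of
length $d$ implies the exponential-decay rate $M = -\ln\varphi / d$,
the only form consistent with defining the rate from a segment survival
probability and a bounding distance; it inverts exactly
($e^{-Md} = \varphi$) and is multiplicative over segment splits. With the
default survival tables, the HCB–ADM segment (25 km) is the mortality
hotspot for every group-year — its per-km rate is several-fold the other
marine segments', consistent with a migration disruption at the bridge.

Per-population segment distances are configuration: PR–RM 0.05 km (Big
Beef), 1.9 km (Duckabush), 13.5 km (Skokomish); RM–HCB 75 km for the
Skokomish mouth, 24 km for Big Beef Creek (which enters northern Hood
Canal), and 25.6 km for the Duckabush (1.6 km south of Big Beef); HCB–ADM
25 km and ADM–JDF 110 km for everyone. The Big Beef and Duckabush RM–HCB
values are this package's reading of the published 24–75 km span plus the
1.6 km offset; they affect only the mortality-rate scaling, never the
survival estimates.

## Behavior statistics

* **G-test.** Estuary-detection counts for smolt-index-1 fish versus
  index-2/3 fish form a 2×2 table tested with the likelihood-ratio
  statistic $G = 2\sum O \ln(O/E)$ divided by the Williams correction
  $q = 1 + (n/R_1 + n/R_2 - 1)(n/C_1 + n/C_2 - 1)/(6n) \ge 1$ ("adjusted
  G" in the standard biometry usage; the source does not expand the
  subscript, and this is the reading adopted). Under null simulation at
  the observed margins the test's type-I error at $\alpha = 0.05$ is
  0.049.
* **Two-way models.** Travel rates and migration range are analysed with
  fixed-effects least squares (`rearing type × year`), Type-III partial
  sums of squares under sum-to-zero contrasts — the source does not state
  its SS type, which is the main reason its printed F statistics are not
  numeric targets here. An empty cell leaves the interaction inestimable
  and flagged.
* **Tukey–Kramer.** Pairwise rearing-type contrasts within each year,
  gated on a significant interaction ($P \le 0.05$, mirroring the
  conditional procedure), using the studentized range over the full set
  of cell means with the harmonic-mean correction for unbalanced cells;
  verified against `stats::TukeyHSD` on balanced designs.
* **Travel rates** use *first* detections at each bounding line (the
  standard convention; the source does not say first versus last).
  Migration range is the corridor distance from the Skokomish estuary to
  the northernmost detection, 0 for estuary-only fish, undefined (NA,
  never 0) for undetected fish.

## The simulator's stated world

Defaults reproduce the emulated study design: ten (population, year) tag
groups totalling 302 fish with published cohort moments — fork length
normal around the group mean with SD recovered as $SE\sqrt{n}$, weight
through a normal Fulton condition factor $K = 10^5 w/L^3$ (SD 0.05, a
typical within-group spread) so condition is recomputable from length and
weight, release days uniform in each group's window, and smolt index
drawn from a per-group simplex matching the printed mean (wild and
Duckabush fish never score 1; Skokomish hatchery groups put 10–30% of
mass on index 1, consistent with the reported unsmolted fraction).
Generating survival is the published six-row group-year table; detection
is river-mouth-specific (0.928 Big Beef, 0.415 Skokomish, 0.489
Duckabush) with shared HCB 0.767, ADM 0.757 and fixed JDF 0.685.

Three choices deserve explicit defense:

* **Residualization defaults to off.** The generating survival values are
  *apparent* survival estimates, which already fold non-migrants into
  $1-\varphi_1$. Turning smolt-index-linked residualization on by default
  would double-count it. The knob (`residual_prob_by_si`, high for index
  1) exists for behavior-focused runs, where residuals produce
  no marine detections and shrink hatchery migration ranges and northern
  receiver densities — the qualitative contrast the density plots show.
* **Travel speeds** are lognormal around 10 km/day (SD 4) in freshwater
  and 15 km/day (SD 5) at sea — field-realistic magnitudes for actively
  migrating steelhead smolts; the source reports rates only as outputs,
  not as a generating model. Rates are exposure-parameterized by their
  mean, so simulated travel-rate recovery targets the configured mean.
* **Behavioral receivers** (no encounter occasion) are passed by any fish
  whose survived extent spans them and log events with probability 0.5,
  purely to exercise the migration-range and density logic.

What a green test does **not** establish: the simulator draws independent
fates per fish (except the explicit frailty knob), has no tidal or diel
detection variation, no route structure between lines, and no
year-to-year receiver outages; real telemetry data violate all of these
to some degree. Recovery tests certify the estimator against its own
generating assumptions, and the consistency checks certify the arithmetic
of the published tables — not that the published field estimates are
reproducible from raw data, which were never deposited.

## Numerical choices, in one place

* Logit link for $\varphi$ and $p$; $\beta = 0$ start; BFGS, reltol
  $10^{-12}$, up to 3 jittered restarts.
* Aliasing: greedy left-to-right column retention via rank checks
  (tolerance $10^{-8}$); dropped names logged on the design object.
* Fixed cells: real-scale values substituted after the link; never
  estimated, never counted as reals.
* GOF pooling threshold: expected count 2; 2×2 components that still
  fail it are dropped, and zero estimable df yields $\hat c = 1$ with a
  warning.
* $0 \ln 0 = 0$ convention in the G-test; zero margins are flagged NA
  rather than computed.
* Ties in the occasion-collapse are irrelevant by construction: histories
  are presence/absence, so duplicate events are idempotent.
* Seeds: cohort generation uses the configured seed; fate/event
  generation uses `seed + 7` (mod $2^{31}$) so the two stages are
  independently reproducible.
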