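---
title: "Modelling international mobility flows with gravity, radiation and stringency-aware regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling international mobility flows with gravity, radiation and stringency-aware regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mobiflux)
```

## The problem

Operators of a national mobile network observe an *egocentric star* of
international flows: for every counterpart country and every day, a count
of foreign devices roaming in (incoming) and of domestic devices roaming
abroad (outgoing). Such panels are a timely proxy for international
mobility, but they raise two modelling questions this package addresses:

1. How well do the classical spatial-interaction models — gravity and
   radiation — describe daily international flows, especially once
   governments start imposing travel restrictions?
2. Can a model that *sees* the restrictions do better? We answer with a
   stringency-aware gravity regression: a negative-binomial (NB) model of
   daily counts on log-populations, a distance term, and the 0–100 policy
   Stringency Index (SI) of origin and destination.

Because operator roaming data are proprietary, everything here is
validated on synthetic worlds whose generating mechanism is under our
control; the package ships the generator as first-class, tested code.

## Models and their assumptions

### Gravity

`T_ij = K · P_i · P_j · f(r_ij)`, with `f(r) = exp(−β r)` (β in km⁻¹) or
`f(r) = r^(−β)` (β dimensionless). Assumptions: flows scale linearly in
each population mass and decay monotonically with great-circle distance;
no competition between destinations; one scale `K` (the unconstrained
form — no production/attraction constraints).

**Fitting.** `(K, β)` minimise the sum of squared residuals on the raw
count scale. We solve the problem by *variable projection*: for fixed β
the optimal scale has the closed form `K(β) = Σ y·g / Σ g²` with
`g = P_i P_j f_β(r)`, so the search is a one-dimensional Brent
minimisation over β ≥ 0. This is deterministic, immune to the poor
conditioning of a joint `(K, β)` search (typical `K` values are around
1e-9 while β is around 5e-3), and recovers noiseless parameters to
essentially machine precision. Raw-scale least squares weights large
flows most — appropriate when the biggest corridors matter most; it is
*not* a maximum-likelihood count fit (the NB regression plays that role).

**Degeneracy.** If all distances are equal, `f_β(r)` is absorbed entirely
by `K` and the residual surface is flat in β. Flatness is detected by
probing the profiled objective at five β values and comparing its range
to `1e-10 · Σ y²` (the objective's natural scale — a threshold relative to
the probe maximum would misfire when the fit is exact and the surface sits
at rounding-noise level). A flat fit returns the reference
β (1/median(r) for exponential, 1 for power) with a
`mobiflux_flat_residual_warning`.

**Fit scope.** Per-day fits (the default in the pipeline) give each
calendar day its own `(K, β)` — a descriptive, in-sample protocol that
tracks level shifts day by day. A pooled `global` fit is available and is
the honest "stringency-blind" baseline when comparing against the
stringency-aware model, which is itself pooled across days.

### Radiation

The parameter-free score
`p_ij = P_i P_j / ((P_i + s_ij)(P_i + P_j + s_ij))`, where the
*intervening opportunities* `s_ij` sum the populations strictly closer to
the origin than the destination (excluding both endpoints). A variant
with `(P_j + s_ij)` in the first factor circulates in parts of the applied
literature; both are implemented (`first_factor = "standard"` /
`"as_printed"`), the choice is explicit, and the two coincide whenever
`P_i = P_j`. Ties at exactly `r_ij` are resolved by the `radius_rule`
(`strict` by default) so results are deterministic.

Scores are turned into flows by scaling each origin's scores to a total
outflow `O_i`. On an egocentric star the true `O_i` of a counterpart
country is unobservable; the pipeline uses the country's *observed* flow
toward the hub that day as `O_i`, redistributes it over the full
destination universe, and compares only the hub-pointing component with
the data. This is a deliberately conservative convention: the radiation
prediction for a spoke origin is always ≤ its observed value, and the
model is rewarded only for placing a large share of each origin's outflow
on the hub. The optional finite-size correction replaces the normalising
sum by `1 − P_i/M` (M = total population).

### Stringency-aware NB regression

```
E[T_ij] = exp(ε + α log P_i + β log P_j + γ x(r_ij) + δ₁ SI_i + δ₂ SI_j)
```

with `x(r) = log r` for the power family and `x(r) = r` (km) for the
exponential family. Writing the distance covariate this way — rather than
plugging a pre-parameterised deterrence function into the regression —
keeps the decay rate identifiable: γ *is* the (negative) power-law
exponent, or the (negative) exponential rate, and both decay families are
reproduced exactly. SI enters in raw 0–100 units, so δ's are
per-index-point effects on log flow. Mass exponents α, β are free rather
than pinned to 1. Counts are NB with dispersion θ
(`Var = μ + μ²/θ`, the mean/shape convention — stated explicitly because
the other convention, `size/prob`, is a classic trap); θ is estimated by
maximum likelihood with alternating IWLS/θ updates (`MASS::glm.nb`). Zero
counts are legitimate observations and are never dropped.

Two numerical edge cases are handled rather than failed:

* **Constant covariates.** Fitted per direction on a star, one endpoint of
  every record is the hub, so its log-population is constant and cannot be
  separated from the intercept. Such columns are absorbed into the
  intercept (coefficient reported as 0, standard error `NA`, names listed
  in `$absorbed`, a `mobiflux_constant_covariate_warning` signalled).
  Predictions are unaffected while the covariate stays at that constant.
  Genuine collinearity among varying covariates remains a
  `mobiflux_singular_design_error`. Consequence: full recovery of *all
  six* coefficients requires pooling both directions, which is what
  `recovery_experiment()` does by default.
* **The Poisson limit.** When the data are (near-)equidispersed the ML
  iteration for θ diverges (θ → ∞). The NB model then degenerates to
  Poisson regression, which is returned as the limit fit (dispersion
  `Inf`, `mobiflux_poisson_limit_warning`). This also gives the package a
  well-defined behaviour exactly where the NB and Poisson fits provably
  agree.

Directions are fitted separately in the pipeline (incoming and outgoing
flows are different processes under asymmetric restrictions), pooled over
all days — identification of δ's needs temporal SI variation, so per-day
NB fits are not offered.

## Evaluation metrics

* **CPC** `= 2 Σ min(g, r) / (Σ g + Σ r)`: symmetric, scale-invariant,
  in [0, 1]; equals the fraction of correctly allocated unit trips when
  the two totals match (verified in the tests against a brute-force trip
  matcher). Both totals zero is *undefined* and returns `NA_real_`, never
  0/0.
* **IG** `= Σ (y_r/N) log(y_r / y_g)` with natural log and the
  `0·log 0 = 0` convention; non-negative whenever totals match (Gibbs'
  inequality), and reported as-is (it can be negative when totals differ —
  that is a property of the definition, not a bug). A generated zero
  against a positive observation would be infinite; generated entries are
  floored at a configurable `floor_eps` (default 1e-10, far below any
  plausible device count) and the number of floored entries is reported.
* **Relative improvement** `rel(ŷ, y) = (ŷ − y)/y`, applied per day and
  then averaged (average-of-ratios).
* **Period split**: evaluation summaries report mean CPC over P1 (through
  2020-03-15, before most stringency ramps in the default scene) and P2
  (after), both overridable.

Per day, the pair universe is exactly the set of observed
(origin, destination) pairs that day; a model predicting pairs outside it,
or missing observed days, is an error, never a silent drop.

## Synchrony

Global synchronicity `ρ_g` is the Pearson correlation of two aligned daily
series over the full window; local synchronicity slides windows of
W ∈ {5, 10, 15, 20, 25} days in steps of 1 day (overlapping windows — the
finest available protocol) and reports mean and median per W. Zero-variance
windows are undefined and *excluded* from the aggregates (setting them to 0
would bias the mean toward zero), with the exclusion count reported.
Windows below 3 days are refused as unstable. `W = length(series)` reduces
exactly to `ρ_g`, which the tests assert.

## The synthetic generator

`synth_config()` describes the study scene; its defaults are a Europe-like
egocentric world chosen once for realism and identifiability:

| parameter | default | why |
|---|---|---|
| countries | 30 (incl. hub) | enough spokes for stable fits, desk-scale |
| hub | 67e6 people at (54, −2) | UK-like mass and position |
| spoke populations | log-normal, median 1e7, log-sd 0.8 | country-scale spread |
| geometry | lat 36–62, lon −10–25 | European distance scales (300–3500 km) |
| window | 2020-03-05 … 2020-06-02 (90 days) | spans the NPI introduction |
| interventions | start uniform 2020-03-01 … 2020-03-20 | staggered country responses |
| SI trajectory | 0, linear 14-day ramp, plateau U(60, 90) | stylised policy course |
| flow model | NB regression truth (0.8, 0.7, −1.5, −0.02, −0.03) | strong distance decay, mild per-point SI effects |
| noise | NB, dispersion 5 | strongly overdispersed counts |
| scale | calibrated so the median pre-intervention mean flow is 1000/day | flows of order 10²–10⁵ |

The scale (`ε` or `K`) is calibrated deterministically from the world
geometry when left `NULL`, and the resolved value is part of the returned
truth. SI is exactly 0 before each country's intervention date; a
zero-length ramp is a step. All generation is seeded and bit-reproducible;
the generator also emits the noiseless mean surface, which the tests check
against `gravity_predict()`/`cgm_predict()` to 1e-10 (cross-module
consistency).

For the gravity parameter-recovery experiments the scene is a 40-location
star with a tighter box (lat 44–60, lon −6–16) and population log-sd 0.5,
with Poisson noise around an exponential-decay surface (β = 0.005 km⁻¹):
the tighter spread keeps the mean flows in roughly the 10²–10⁴ range so
that no single corridor dominates the least-squares objective.

**What the generator does not emulate** — and hence what passing tests do
*not* show about real roaming data: multi-SIM and multi-operator double
counting, dual citizens and long-stay residents, day-of-week and holiday
seasonality, measurement gaps, within-country movement of roamers,
airline-network structure (the synthetic reference series is by
construction a noisy copy of the aggregate, so its high synchrony
validates the synchrony *machinery*, not roaming data), and any deviation
of real flows from the NB-around-log-linear mean assumption. Parameter
recovery on these worlds demonstrates correctness of the estimators under
the model, not the model's truth in the field.

## Reported experiment sizes

The test suite and `scripts/acceptance.R` use: 20-seed recovery runs at
30 countries × 90 days (NB regression, both directions pooled, n = 5220
per fit) and 40 locations × 10 days (gravity, Poisson); 20 replicate
worlds for the stringency-aware vs stringency-blind CPC comparison
(incoming direction, pooled fits for both competitors); 20 random general
OD worlds of 5–25 locations for the radiation brute-force equivalence; 100
random vectors for the metric-oracle equivalence; and an 8-country,
20-day world for the end-to-end pipeline determinism check. These sizes
were chosen as the package's standard desk-scale experiment battery.

## Known limitations

* The gravity fitter is least-squares, not ML; its `β` carries no
  standard error (the NB regression is the inferential tool).
* Radiation's `O_i` convention on egocentric stars (observed hub-bound
  flow as total outflow) is one defensible choice among several; with it,
  radiation can never over-predict a spoke origin's hub-bound flow.
* The stringency covariates are the composite index only; no
  per-indicator decomposition (school closures, travel bans, …).
* Wald 95% intervals from the NB fit are asymptotic; coverage is verified
  empirically at the default scene, not guaranteed at much smaller n.
* Country centroids and the haversine metric (sphere radius 6371 km) are
  a coarse geometry for large countries; finer resolutions would need
  sub-national centroids.
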