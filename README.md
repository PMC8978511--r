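# mobiflux

Spatial-interaction modelling of **daily international mobility flows**
observed on an egocentric (hub-centred) origin–destination network — the
situation of a single national mobile operator watching foreign SIM cards
roam onto (and its own SIMs roam off) its network. The package is aimed at
epidemiological and mobility modellers who need to fit, compare and
validate flow models on such panels, in particular across the introduction
of COVID-era non-pharmaceutical interventions (NPIs), when classical
models that only see population and distance break down.

## Models

For locations *i, j* with populations *P_i, P_j* at great-circle distance
*r_ij* (km):

* **Gravity model** — `T_ij = K · P_i · P_j · f(r_ij)` with deterrence
  `f(r) = exp(−β r)` (exponential) or `f(r) = r^(−β)` (power). `(K, β)`
  are estimated by nonlinear least squares on raw counts, per day or
  pooled.
* **Radiation model** — parameter-free:
  `T_ij ∝ P_i P_j / ((P_i + s_ij)(P_i + P_j + s_ij))`, where `s_ij` is the
  total population strictly closer to the origin than the destination.
  A variant with `(P_j + s_ij)` in the first factor, which circulates in
  parts of the applied literature, is available explicitly
  (`first_factor = "as_printed"`).
* **Stringency-aware gravity (CGM)** — a negative-binomial regression
  with log link:

  ```
  E[T_ij] = exp(ε + α·log P_i + β·log P_j + γ·x(r_ij) + δ₁·SI_i + δ₂·SI_j)
  ```

  where `x(r) = log r` (power family) or `x(r) = r` (exponential family)
  and `SI` is the 0–100 policy Stringency Index of the origin and
  destination on that day. `δ₁, δ₂` are per-index-point log-flow effects;
  the dispersion θ (variance `μ + μ²/θ`) is estimated by maximum
  likelihood.

Model quality is scored per day by the **Common Part of Commuters**
(Sørensen–Dice similarity; equals allocation accuracy when totals match)
and the **Information Gain** (a KL-style non-negative error), with
period-split summaries (pre/post NPI introduction). A **synchrony** module
computes global and sliding-window Pearson correlations between a mobility
proxy and an external reference series (e.g. air-passenger arrivals), and a
fully seeded **synthetic-world generator** makes every claim testable
without proprietary roaming data.

## Worked example

```r
library(mobiflux)

cfg   <- synth_config(seed = 42)        # 30 countries x 90 days, NB flows
world <- generate_world(cfg)
sim   <- simulate_flows(world)          # both directions of the star

design <- build_design(sim$panel, world$locations, world$stringency,
                       kind = "power", dist = world$dist)
fit <- cgm_fit(design)
print(fit)
#> <cgm_fit> kind=power  n=5220  logLik=-24212.63  theta=4.864
#>   epsilon=-8.2188 alpha=0.8122 beta=0.7035 gamma=-1.5107 delta1=-0.01917 delta2=-0.03066
```

The generating truth for this seed was
`(ε, α, β, γ, δ₁, δ₂) = (−8.017, 0.8, 0.7, −1.5, −0.02, −0.03)`: every
coefficient is recovered to a few percent, and the fitted `δ`s say that
each additional stringency point at the origin (destination) multiplies
the expected flow by `exp(−0.019)` (`exp(−0.031)`).

```r
ev <- evaluate_models(list(cgm = cgm_predict(fit, design)), sim$panel)
ev$summary
#>   model mu_cpc max_cpc min_cpc mu_cpc_p1 mu_cpc_p2  mu_ig
#> 1   cgm  0.812   0.903   0.735     0.831      0.81 0.0956
```

i.e. on average 81% of all trips are allocated to the correct
origin–destination pair, slightly higher before the stringency ramps (P1,
through 2020-03-15) than under them (P2). A constructed reference series
(scaled aggregate flow + 5% noise) is near-perfectly synchronous with the
aggregated panel:

```r
ref <- generate_reference_series(sim$panel, scale = 0.85,
                                 noise_sd_fraction = 0.05, seed = 43)
global_synchrony(aggregate_daily_total(sim$panel, "incoming"), ref)
#> [1] 0.999
```

## Command line

A thin CLI over the same functions lives in `inst/cli/mobiflux.R`
(subcommands `synth`, `fit-gravity`, `fit-cgm`, `predict-radiation`,
`evaluate`, `synchrony`, `pipeline`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","mobiflux.R",package="mobiflux"))')" \
  pipeline --seed 1 --out-dir results/run1
```

`pipeline` writes `summary.csv` (one row per model × direction, CPC/IG
period summaries), `daily_metrics.csv`, `synchrony.json`, per-model
predictions, the generated input data and a run manifest. Reruns with the
same config are byte-identical.

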