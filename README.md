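# seabycatch

Bayesian spatiotemporal hurdle modelling of seabird bycatch in pelagic
longline fisheries.

Seabird bycatch in longline fleets is a rare event — in the U.S. Atlantic
pelagic longline fishery that motivates this package, fewer than 1% of
observed sets catch a bird — yet it is spatially clustered, drifts between
years, and must be extrapolated from a small observer sample to fleet-wide
logbook effort. `seabycatch` implements the full analysis chain for this
problem, exercised end-to-end on synthetic data because the underlying
observer and logbook records are confidential:

* **Hurdle model**: occurrence is Bernoulli with
  `logit(p) = intercept + Σ f_i(c_i) + Σ s_j(x_j) + u_vessel + ξ(s)`
  (sum-to-zero categorical effects, RW1 smooths, vessel random effects, a
  spatial field constant over years or replicated per year); positive counts
  are zero-truncated Poisson with log link on the untruncated rate λ.
  Expected bycatch per set is `p · λ / (1 − e^{−λ})`.
* **Barrier spatial field**: Matérn (ν = 1) Gaussian field via the SPDE/GMRF
  finite-element construction, with a *barrier* variant whose correlation
  range collapses inside land polygons so correlation cannot travel across
  coastlines. Assembled as sparse precision matrices, validated against a
  dense-inverse oracle and the closed-form Matérn correlation
  `κ d K₁(κ d)`.
* **Inference**: Laplace approximation at the latent mode with a coarse
  hyperparameter grid (penalised-complexity priors), DIC/WAIC per
  sub-model, and forward stepwise selection under the Δ ≥ 5 rule with the
  spatial field offered last.
* **Fleet extrapolation**: posterior draws score every logbook set; totals
  by year/zone/season/target are summed within draws and summarised across
  draws (mean, sd, CV).
* **Hotspots and climate**: annual hotspot = argmax of a year's
  posterior-mean field; hotspot latitude is cross-correlated with an annual
  climate index at lags 0..K (significance at ±1.96/√n), recovering a
  planted lag-2 dependence end-to-end.
* **Mitigation simulation**: six fleet-behaviour scenarios remove or
  redistribute sets (redistribution ≥ 50 miles from every hotspot cell),
  scoring % change in predicted bycatch and per-species fish catch against
  the same-posterior baseline.
* **Synthetic data generator**: stylised coastline domain with six fishing
  zones, effort concentrated in a few zones, published effect directions,
  calibrated 0.5% positive-set rate, climate-driven hotspot latitude, and
  shelf-break tuna concentration.

## Worked example

The numbered scripts under `analysis/` run the study end-to-end at a
desk-scale emulation (26 years, 250,000 logbook sets, 8% observer
coverage); each is independently runnable and fully seeded. For a quick
interactive taste:

```r
library(seabycatch)

domain  <- gen_domain(1)
truth   <- truth_params()                       # 0.5% positive sets
climate <- gen_climate_series(1990:2015, seed = 2)
fleet   <- gen_fleet(domain, truth, 20000, 2000:2015, seed = 3)
sampler <- make_bump_field_sampler(domain, truth, climate, 2000:2015, seed = 4)
obs     <- gen_observer_data(fleet, truth, sampler, domain,
                             coverage = 0.25, seed = 5)
mean(obs$bycatch > 0)
#> [1] 0.0034

des <- build_design(obs, model_terms(factors = "season", linears = "water_temp"),
                    "occurrence")
fit <- fit_bernoulli(des)
effect_estimates(fit)$water_temp
#>        level       mean        sd
#> 1 water_temp -0.1271995 0.1029594   # negative: colder water, more bycatch
```

Running the pipeline drivers prints, among other things:

```
$ Rscript analysis/01_simulate.R
fleet: 250000 sets over 26 years; observer: 20000 sets, 89 positive (0.45%), 167 birds
effort concentration: top five zones hold 91.9% of sets

$ Rscript analysis/02_mesh_spde.R
mesh: 462 nodes, 840 triangles (58 barrier-flagged)
correlation across the coastline 0.034 vs open water 0.205

$ Rscript analysis/04_predict.R
fleet-wide expected bycatch: 2444 birds (CV 13.9%) over 250000 sets

$ Rscript analysis/05_hotspot_climate.R
lag-2 correlation between hotspot latitude and the index: r = 0.43 (n = 25), significant at 5%
```

Stage 3 writes the stepwise ladder (model, DIC_z/DIC_y/WAIC_z/WAIC_y per
accepted step; at this scale it selects target species, season, set time,
the vessel effect and the spatial field for the occurrence sub-model),
stage 6 the six-scenario comparison (hotspot-plus-season removal strongest,
3.6% bycatch reduction; redistribution scenarios cost an order of magnitude
less catch than removals).

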