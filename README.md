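# migrniche

Tools for studying the migration phenology and seasonal climatic niche of
satellite-tracked migratory birds — the analysis chain used to ask whether a
migrant *tracks* a similar climate year-round or *switches* niche between its
temperate breeding grounds and subtropical non-breeding grounds.

The package is aimed at movement ecologists working with Argos-quality
telemetry. It covers four stages, each usable on its own:

1. **Location-error filtering.** A continuous-time correlated random walk
   (integrated Ornstein–Uhlenbeck velocity) state-space model is fitted by
   Kalman-filter maximum likelihood, with a separate measurement variance per
   Argos location class (LC3…LC0), and positions are re-predicted at the
   original fix times by fixed-interval smoothing (`fit_crw()`,
   `smooth_positions()`).
2. **Migration phenology from net squared displacement (NSD).** The NSD of a
   track — squared distance of each fix from the trajectory origin — is fit
   with logistic ("sigmoid") phenology models (`compute_nsd()`,
   `fit_single_sigmoid()`, `fit_double_sigmoid()`):

   single (spring only):  `NSD(t) = δ / (1 + exp((θ − t)/φ))`

   double (annual):       `NSD(t) = δ/(1 + exp((θs − t)/φs)) − δ/(1 + exp((θa − t)/φa))`

   with asymptote δ (km²), midpoints θ (day of year) and time-elapse scales φ
   (days). `√δ` serves as a model-based migration distance and `2φ` as a
   migration duration surrogate; departure/arrival dates come from analytic
   threshold crossings of the fitted curve (`derive_migration_metrics()`,
   `segment_timing()`).
3. **Movement metrics.** Hourly speeds from 30–60-minute steps, migration trip
   distances, per-animal seasonal summaries with 95% CIs, and
   observed-vs-model regressions (`hourly_speeds()`, `trip_distance()`,
   `summarize_speeds()`, `regress_observed_vs_model()`).
4. **Climatic niche overlap.** Seasonal climates (minimum/maximum temperature,
   precipitation, wind speed) at thinned occurrence locations and their
   background rasters are ordinated by PCA; kernel-smoothed occupancy on a
   100×100 grid over PC1–PC2 yields Schoener's
   `D = 1 − ½·Σ|p₁ − p₂|` and the Hellinger-based
   `I = 1 − ½·Σ(√p₁ − √p₂)²` (`niche_overlap()`, `occupancy_grid()`,
   `schoener_D()`, `hellinger_I()`, `variable_overlap_1d()`).

A seeded synthetic-data module (`sim_config()`, `simulate_migratory_path()`,
`corrupt_with_argos_error()`, `simulate_climate_fields()`) generates
Argos-like trajectories and seasonal climate fields with known truth, so every
stage can be validated end to end without proprietary tracking data.

## Worked example

Simulate one annual cormorant-like track with Argos noise, estimate its
migration phenology, and test for seasonal niche separation:

```r
library(migrniche)

cfg <- sim_config()  # Gulf-coast winter range, northern-plains summer range
track <- simulate_migratory_path(cfg, animal_id = "cormorant01", seed = 42)
track <- corrupt_with_argos_error(track, cfg, seed = 43)
track
#> <cm_track> animal cormorant01: 840 fixes, 2000-01-01 00:00 to 2000-12-29 05:00
#>   Argos classes: LC0=345, LC1=236, LC2=164, LC3=95

series <- compute_nsd(track)
fit <- fit_double_sigmoid(series)
fit
#> <sigmoid_fit> double model, animal cormorant01, converged: TRUE
#>               delta     theta_s     theta_a     phi_s     phi_a
#> estimate 3781280.00 118.6620000 274.2870000 1.8773000 2.1265200
#> se          3119.27   0.0222458   0.0327567 0.0194913 0.0323642
#>   residual SD 4.245e+04 km^2

m <- derive_migration_metrics(fit)
m$sqrt_delta_km   # model-based migration distance: 1944.6 km
m$two_phi         # duration surrogates: spring 3.75, autumn 4.25 days

segment_timing(series, fit)
#> <migration_timing>
#>   spring_departure    111.78
#>   spring_arrival      125.54
#>   autumn_departure    266.50
#>   autumn_arrival      282.08
#>   autumn_duration      15.58
#>   spring_duration      13.76
```

The fitted asymptote corresponds to a ~1945 km migration (the configured range
centres are ~1950 km apart), and the threshold-crossing dates bracket the
configured migration windows (days 110–125 and 270–285).

```r
rasters <- simulate_climate_fields(climate_config(), seed = 44)
thinned <- thin_daily(track, seed = 45)
thinned$season <- season_from_months(thinned$time)
ov <- niche_overlap(thinned[which(thinned$season == "winter"), ],
                    thinned[which(thinned$season == "summer"), ],
                    rasters$winter, rasters$summer)
c(D = ov$D, I = ov$I, wind = ov$wind_overlap)
#> Schoener D = 0.00, Hellinger I = 0.00, wind overlap = 0.82
ov$explained[1:2]
#> PC1 73.04%, PC2 24.55% of climate variance
```

Under the default climate configuration — seasonal temperatures and
precipitation strongly separated, wind speeds nearly identical — the seasonal
niches are disjoint in PC space (D = I = 0, a niche switcher) even though the
one-dimensional wind distributions overlap strongly, the signature pattern
this analysis is designed to detect.

`run_pipeline(pipeline_config(seed = 1))` chains all stages (simulation,
filtering, thinning, NSD fitting, timing, speeds, niche overlap) and can write
every report plus a manifest to a directory.

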