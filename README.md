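# remeval

Density estimation for unmarked wildlife with the random encounter model
(REM), together with the simulation and movement-modelling machinery needed
to test what happens when the REM's sampling requirements are violated.

The package is aimed at camera-trap ecologists who estimate predator and
prey densities from photographic detections — and who need to know how much
an estimate moves when cameras are placed on travel routes instead of at
random, or when the movement-velocity (day range) input is borrowed from
another study, species, or season rather than estimated for the surveyed
population.

## The model

The REM inverts the ideal-gas encounter rate between moving animals and the
sector-shaped viewshed of a camera (radius *r*, arc *θ*):

```
D = (y / t) * pi / (v * r * (2 + theta))
```

where `y/t` is the trap rate (independent detections per camera-day), `v`
the day range (km/day), `r` the detection radius (km) and `theta` the
detection arc (radians). Confidence intervals come from a percentile
bootstrap over cameras. The day range is estimated from GPS telemetry by
fitting continuous-time movement models (BM, OU, IOU, OUF) with exact
Gaussian likelihoods, selecting by AICc, and converting the fitted per-axis
velocity variance σ_v² to a mean scalar speed through the Rayleigh mean
σ_v·√(π/2); velocity is estimable only when a correlated-velocity family
(IOU or OUF) wins the selection.

Six scenarios cross the camera subset (random / strategic / both) with the
velocity specification (stratum mean, or that mean ±20 % to mimic a borrowed
value); each non-Baseline estimate is summarised as a percent relative
difference (%RD) from the Baseline (random cameras, stratum-mean velocity).
A literature-trend module fits Poisson and negative-binomial GLMs to yearly
study counts and reports per-year rate ratios.

## What is in the package

| Area | Functions |
| --- | --- |
| Movement simulation | `movement_params`, `sample_track`, `sample_biased_track`, `sample_ballistic_track`, `landscape` |
| Cameras & photos | `place_cameras_random`, `place_cameras_strategic`, `simulate_photos`, `burst_spec` |
| Day-range estimation | `empirical_variogram`, `thin_track`, `fit_ctmm`, `select_model`, `mean_speed`, `aggregate_speeds` |
| Detections | `standardize_bursts`, `group_detections`, `camera_effort`, `count_table` |
| REM | `rem_density`, `bootstrap_rem`, `run_scenarios`, `percent_rd` |
| Literature trends | `tabulate_counts`, `fit_count_glm`, `rate_ratio_ci`, `predict_marginal`, `review_tally` |
| Orchestration | `run_experiment` (YAML config in, CSV/JSON bundle out); thin CLI in `inst/scripts/remeval-run.R` |

## Worked example

```r
library(remeval)

counts <- data.frame(species = "prey", season = "summer",
                     year_label = "summer 2020", placement = "random",
                     camera_id = sprintf("R%d", 1:5),
                     y = c(12, 3, 0, 7, 22), t = c(30, 28, 31, 14, 30))
speeds <- data.frame(species = "prey", year_label = "summer 2020",
                     mean_day_range_km = 8.24)
res <- run_scenarios(counts, speeds, n_iter = 1000, seed = 1)
res[res$camera_subset == "random",
    c("scenario", "velocity_multiplier", "point", "ci_low", "ci_high",
      "percent_rd")]
#>          scenario velocity_multiplier     point   ci_low  ci_high percent_rd
#> 1        Baseline                 1.0  9.119811 2.738414 16.35313    0.00000
#> 3 Random+Borrowed                 0.8 11.399763 3.393628 20.44141   25.00000
#> 4 Random+Borrowed                 1.2  7.599842 2.262419 13.78335  -16.66667
```

(The strategic scenarios are skipped with a warning because this count table
has no strategically placed cameras.)

Reading the output: with a trap rate of 44 detections over 133 camera-days,
a day range of 8.24 km/day and the default detection zone (r = 5 m,
θ = 0.7661 rad), the Baseline density is 9.1 animals/km² with a bootstrap
95 % CI of (2.7, 16.4). Feeding the same counts a day range 20 % too small
inflates the estimate by exactly +25 %; one 20 % too large deflates it by
−17 % — the misspecification bias is analytic (D ∝ 1/v) and independent of
the counts.

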