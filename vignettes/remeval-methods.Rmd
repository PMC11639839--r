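---
title: "Methods: REM density estimation and its failure modes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: REM density estimation and its failure modes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remeval)
```

## The estimator and its assumptions

The random encounter model (REM) treats animals as ideal-gas particles:
individuals move independently of one another and of the cameras, with
uniform stationary position density $D$ and mean scalar speed $v$, and a
camera detects perfectly inside a sector of radius $r$ and arc $\theta$.
Under those assumptions the expected rate of sector entries per camera is

$$ g = D \, v \, r \, \frac{2 + \theta}{\pi}, $$

so a trap rate $y/t$ (independent detections per camera-day) inverts to

$$ \hat D = \frac{y}{t} \cdot \frac{\pi}{v \, r \, (2 + \theta)}. $$

Everything this package evaluates flows from the two fragile inputs of that
inversion: the requirement that cameras sample space randomly (so that the
trap rate reflects $D$ rather than preferential use of the camera sites),
and the day range $v$, which enters inversely, so a $-20\%$ error in $v$
inflates $\hat D$ by $+25\%$ and a $+20\%$ error deflates it by $-17\%$ —
an identity that holds for any count table.

`rem_density()` implements the inversion; `bootstrap_rem()` adds percentile
confidence intervals by resampling whole cameras with replacement (1000
iterations by default, seeded). The point estimate pools counts and effort
($\sum y_i / \sum t_i$), which weights cameras by effort; an unweighted
mean of per-camera densities is available via `statistic = "mean"`. The two
coincide under equal effort. We chose pooling as the default because the
trap rate is the sufficient statistic of the Poisson encounter process;
the alternative is provided because the bootstrap literature for the REM
does not commit to either.

`run_scenarios()` crosses camera subsets (random / strategic / both) with
velocity specifications (stratum mean; mean scaled by 0.8 and 1.2 as a
stand-in for a borrowed day range) and reports each scenario's percent
relative difference from the Baseline (random cameras, stratum mean).
Borrowed-velocity scenarios deliberately report both the low and high
estimate rather than averaging them.

## Movement processes

Four isotropic Gaussian processes describe telemetry, in increasing order
of structure:

* **BM** — Brownian motion, per-axis increment variance $2 D \Delta$;
* **OU** — mean-reverting position (home range, timescale $\tau_p$),
  uncorrelated velocity;
* **IOU** — integrated OU: autocorrelated velocity (timescale $\tau_v$,
  stationary per-axis velocity variance $\sigma_v^2 = D/\tau_v$) without
  home-range reversion;
* **OUF** — home range plus autocorrelated velocity; position
  autocovariance
  $\sigma_p^2 (\tau_p e^{-t/\tau_p} - \tau_v e^{-t/\tau_v}) / (\tau_p - \tau_v)$,
  velocity variance $\sigma_v^2 = \sigma_p^2/(\tau_p \tau_v)$.

Both axes share parameters (isotropy), matching the fitted model class.

**Simulation** (`sample_track`) uses the exact discrete-time Gaussian
transition of each family — for the two-state families the state
$(x, \dot x)$ is propagated through the matrix exponential of the drift,
with innovation covariance $\Sigma_\infty - \Phi \Sigma_\infty \Phi^\top$
(stationary families) or the closed-form integrated-OU covariance — so
there is no Euler bias at any step size. Stationary families initialise
from the stationary law; BM/IOU start from a point and reject a stationary
initialisation request. The recursion is decoupled through the drift
eigenbasis into AR(1) components so long paths simulate in vectorised time.

**Corridor bias** (`sample_biased_track`) switches to Euler–Maruyama so a
drift term can be added: within `attraction_range` of a corridor polyline
the velocity equation gains an acceleration of magnitude
`attraction_strength * sigma_v` pointing at the nearest corridor point.
This is the simplest mechanism that concentrates utilisation on travel
routes without altering the marginal speed scale. The coefficient has
units 1/s; because the induced drift speed is roughly
$a\,\sigma_v/\gamma$ with $\gamma = 1/\tau_p + 1/\tau_v$, sensible values
are of order $\gamma$ (for the prey-like defaults used in the tests,
$a \in [0.0005, 0.002]$ moves the within-50-m corridor occupancy from
$\approx 10\%$ to $\approx 40\%$). No field estimate of corridor
concentration exists to anchor this knob; it is a free simulation
parameter, and only the *sign* of its effect on strategic-camera trap rates
is treated as a testable claim. The integrator refuses steps coarser than
$\tau_v / 10$.

**Ideal-gas movers** (`sample_ballistic_track`) travel at constant speed
with specular reflection in a rectangle, optionally redrawing their heading
at Poisson times (`turn_rate`). Position is uniform and heading uniform
either way, so the encounter-rate formula applies exactly; turning only
decorrelates the counts of nearby cameras, which matters for bootstrap
validity (below).

## Day-range estimation

`fit_ctmm()` maximises the exact Gaussian likelihood of the position series
per axis. Because positions carry no observation error here, the Kalman
filter collapses: OU innovations are AR(1) residuals, and the two-state
families need only a scalar recursion over the latent velocity. Three
numerical choices matter:

* **Conditioning.** All four families are evaluated conditional on the
  first fix, so stationary (OU/OUF) and nonstationary (BM/IOU) families are
  compared by AICc on the same $n - 1$ observations.
* **Profiling.** The overall variance ($\sigma_p^2$, $\sigma_v^2$, or $D$)
  and the home-range centre (via a constant-regressor innovation stream)
  are profiled out in closed form; optimisation is only over log
  timescales, with OUF parameterised as
  $(\log \tau_v, \log(\tau_p - \tau_v))$ so $\tau_p > \tau_v$ by
  construction.
* **Multi-start.** Quasi-Newton (L-BFGS-B) from eight log-spaced starts
  spanning roughly [fix interval / 10, track duration], with hard bounds a
  factor 20 beyond; white-noise-like data drive $\tau_p$ into the lower
  bound, which is the correct degenerate answer.

AICc uses $k = 1, 4, 2, 5$ parameters for BM, OU, IOU, OUF, and ties break
toward fewer parameters. Velocity is reported only when IOU or OUF wins:
$\bar s = \sigma_v \sqrt{\pi/2}$ (the Rayleigh mean of an isotropic
Gaussian velocity), converted to km/day by 86.4. This closed form was
chosen over trajectory-simulation speed estimation because it is
deterministic, exactly testable, and consistent with the fitted model; it
shares the known caveat that coarse fix rates underestimate speed, which is
why model selection gates the estimate.

Pre-processing mirrors field practice: season windows are summer
(1 May–31 October) and winter (1 November–30 April, labelled across the
year boundary), applied in local study time (UTC offset $-8$ h by
default); seasonal tracks need at least 200 (predator) or 100 (prey) fixes,
inclusive, after thinning; `thin_track()` is the greedy forward pass that
never leaves a gap below `target - tolerance`; and `empirical_variogram()`
reports mean squared displacement / 4 per lag bin (per-axis semivariance),
with caller-supplied bin breaks for mixed fix rates.

## Detection processing

Photo records are standardised to a minimum one-minute spacing per
camera-and-species stream (so fast-trigger programmes match slower ones)
and grouped into independent events with a strictly-greater-than gap rule:
a new event starts only when the gap exceeds the discrimination threshold
(default 1800 s predator / 600 s prey). Grouping is purely temporal within
a camera-species stream — animals are unmarked, and thresholds are not
applied across neighbouring cameras. One subtlety is worth recording:
standardisation *refines* the event partition but does not commute with it
in general, because a dropped record can bridge a near-threshold gap; the
tests assert the refinement property rather than the (false) equality.
Camera effort is exact interval arithmetic in fractional days against the
season windows, with overlapping active intervals rejected.

## Simulation designs behind the test suite

The suite's empirical claims are run at sizes chosen to keep the full
check under a few minutes each while leaving clear margins:

* **Encounter-rate and REM recovery.** 8 ballistic movers in a 400 m box
  (true density 50/km², r = 20 m so discretisation loss at a 0.5 s step is
  $\approx 1.5\%$), 10 cameras, 4 h; 100 replicates give a median absolute
  %RD from truth of a few percent against a 10 % bound.
* **Bootstrap coverage.** 50 turning movers in a 1 km box, 30 cameras,
  2.5 h, 200 replicates. Turning matters: with purely ballistic movers one
  animal's straight path sweeps several cameras and correlates their
  counts, which camera-level resampling cannot see (observed coverage
  $\approx 0.80$); with headings redrawn every $\sim 250$ s the counts are
  near-independent and the percentile interval covers at $\approx 0.95$.
  Real surveys sit somewhere between these regimes — the bootstrap's
  camera-exchangeability assumption is a genuine limitation, not a solved
  problem.
* **Strategic inflation.** Six OUF movers over a two-corridor landscape
  with attraction 0.002/s, 12 random vs 12 strategic cameras, 24 h; the
  strategic trap rate exceeds the random one in essentially all replicates.
  Only this sign is claimed; the magnitude depends on the free attraction
  knob.
* **Parameter recovery.** OUF with $\sigma_p^2 = 10^6$ m²,
  $\tau_p = 5000$ s, $\tau_v = 1000$ s, sampled every $\tau_v/5$ for 1000
  fixes (40 range-crossing times — enough that the home-range parameters,
  whose sampling error is dominated by the number of range crossings, are
  identifiable); 50 replicates give median relative errors well under 20 %
  for the parameters and $\approx 2\%$ for the day range.

What passing these tests does **not** show about real data: no telemetry
error (the likelihood has no measurement-noise term), perfect detection
inside the sector (no distance decay), no activity cycles, single-species
independence, and bootstrap validity only as far as camera counts are
exchangeable.

## Literature-trend module

Yearly study counts are zero-filled over 2008–2023 and fitted with log-link
Poisson (`stats::glm`, IRLS) or negative-binomial (`MASS::glm.nb`,
dispersion profiled by ML; variance $\mu + \mu^2/\theta$) regressions, with
year centred at its midpoint for stability; models are ranked by AICc
(counting the NB dispersion as a parameter). The per-year rate ratio is
$e^{\beta_{\text{year}}}$ with Wald intervals — the CI method in the source
material is unstated, and Wald is the conventional default at these sample
sizes. Post-hoc multiple-comparison machinery is deliberately out of
scope; pairwise Wald contrasts carry no multiplicity correction and are
labelled as such. `synthetic_study_records()` builds a stand-in record
table whose *marginal* tallies match the published review (78 predator–prey
estimates; 14 random-camera, half of those borrowed-velocity; 7 satisfying
both requirements, hence 91 % unreliable); its per-year detail is synthetic,
so fitted rate ratios on it are illustrative, not reproductions.

## Orchestration and reproducibility

`run_experiment()` runs the whole pipeline from one YAML config. A single
seed expands to per-stage seeds by a fixed counter offset (placement uses
seed + 1 and seed + 2, individual $i$ of the species list uses
seed + 10 + 2i for its centre and track, the scenario bootstrap uses
seed + 1000 onward), so any stage can be reproduced in isolation and a
rerun of the same config is byte-identical. The run manifest records the
package version, the seed, and the MD5 of the config as written.

## Known limitations

* Day ranges enter the REM as stratum means; individual heterogeneity in
  $v$ is not propagated into the bootstrap.
* The fitted movement likelihood has no telemetry-error term, so it should
  be applied to thinned data where the per-fix error is small relative to
  inter-fix displacement.
* The corridor-attraction mechanism is one of many that produce
  trail-concentrated use; conclusions drawn from it are directional only.
* Season boundaries assume a fixed UTC offset rather than civil local time
  with daylight-saving transitions.
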