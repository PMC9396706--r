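---
title: "Methods: NSD migration phenology and seasonal climatic niche overlap"
author: "migrniche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NSD migration phenology and seasonal climatic niche overlap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migrniche)
```

This vignette documents the models behind `migrniche`, the choices made where
the methodology was genuinely open, and the limits of what the package's
synthetic validation can show about real telemetry data.

## The scientific setting

A long-distance migrant commutes annually between a subtropical non-breeding
(winter) range and a temperate breeding (summer) range. Two questions drive
the analysis: *when and how far* does it migrate (phenology and movement
metrics), and does it *track* a similar climate year-round or *switch* between
different seasonal climatic niches? Satellite telemetry answers both, but only
after its location error is handled and its irregular duty cycle is accounted
for.

## Location-error filtering: the continuous-time correlated random walk

Argos-quality fixes carry kilometre-scale errors that differ by location
class. The filtering model treats each planar axis (an azimuthal-equidistant
projection centred at the first fix; at the scale of a migration corridor this
projection is effectively linear) as an integrated Ornstein–Uhlenbeck process:
velocity $v$ obeys $dv = -\beta v\,dt + \sigma\,dW$ and position integrates
velocity. This is the standard "correlated random walk" for telemetry: over
gaps short relative to $1/\beta$ the animal keeps its heading, over long gaps
the velocity decorrelates and the track behaves diffusively.

Key numerical points:

* **Exact discretisation.** The transition and process-noise matrices over a
  gap $\Delta$ have closed forms in $\beta\Delta$; for $\beta\Delta < 10^{-4}$
  the closed forms cancel catastrophically in floating point, so a third-order
  Taylor branch is used there. Without it, a likelihood optimiser can wander
  into tiny-$\beta$ regions where rounding error fabricates likelihood.
* **Initialisation.** Position starts at the first fix, velocity at zero, both
  with diffuse variance $10^4\ \mathrm{km^2}$; the first fix therefore
  contributes almost no information about the parameters, only its own
  normalising term.
* **Likelihood and fitting.** `crw_loglik()` is the exact Gaussian
  prediction-error decomposition from the Kalman recursion. `fit_crw()`
  maximises it over $\log\beta$ and $\log\sigma$ (box-constrained
  quasi-Newton, relative tolerance $10^{-8}$). The per-class measurement SDs
  are *held fixed* at their configured values (defaults: LC3 0.25, LC2 0.5,
  LC1 1.5, LC0 5 km — standard Argos accuracy tiers). Freeing four
  measurement variances alongside the two process parameters is weakly
  identified at telemetry sample sizes; fixing them matches how error models
  are used in practice and keeps the velocity process identifiable.
* **Smoothing.** `smooth_positions()` runs the Rauch–Tung–Striebel
  fixed-interval smoother on a time grid augmented with any requested
  prediction times (treated as missing observations), so interpolation and
  extrapolation fall out of the same recursion; extrapolated variances grow
  with distance from the data, and a warning marks them.

The test suite checks the likelihood against a brute-force joint-Gaussian
oracle whose covariance is assembled by matrix exponentials and Simpson
quadrature — deliberately *not* the package's closed forms — and checks, over
seeded replicates, that smoothing reduces the median distance to the known
true positions of Argos-corrupted synthetic tracks.

## Migration phenology from net squared displacement

Net squared displacement — the squared distance of each fix from the
trajectory origin, here computed exactly in km² via the azimuthal-equidistant
projection at the first fix — is flat within a seasonal range, rises steeply
during spring migration, plateaus near the squared migration distance, and
returns in autumn. The package fits two logistic descriptions:

$$\mathrm{NSD}(t) = \frac{\delta}{1 + e^{(\theta - t)/\varphi}}
\qquad\text{(single, spring only)}$$

$$\mathrm{NSD}(t) = \frac{\delta}{1 + e^{(\theta_s - t)/\varphi_s}}
 - \frac{\delta}{1 + e^{(\theta_a - t)/\varphi_a}}
\qquad\text{(double, annual)}$$

with asymptote $\delta$ (km²), midpoints $\theta$ (day of year, the time at
which half the asymptote is reached) and time-elapse scales $\varphi$ (days).
The *sign of the second term* is a deliberate choice: a sum of two rising
logistics climbs to $2\delta$ and cannot describe a return migration, whereas
the difference rises to a plateau at $\delta$ between well-separated midpoints
and falls back toward zero — the shape an annual NSD trajectory actually has.

```{r double-shape}
t <- 1:365
curve_vals <- double_sigmoid(t, delta = 2.5e6, theta_s = 135, theta_a = 237,
                             phi_s = 6.1, phi_a = 13.0)
range(curve_vals[170:210]) / 2.5e6  # summer plateau sits at the asymptote
```

**Fitting.** Nonlinear least squares uses the Levenberg–Marquardt trust-region
implementation in `minpack.lm`, with bounds $\varphi \in (10^{-3}, 100)$ days
and $\delta > 0$. Starting values are data-driven: $\delta_0$ from the series
maximum; $\theta_0$ from the interpolated half-asymptote crossing; $\varphi_0$
from the local slope there (a logistic has slope $\delta/4\varphi$ at its
midpoint). Because some birds migrate in nearly a single day
($\varphi \approx 0.1$ at daily sampling), a small deterministic multi-start
over $\varphi_0 \in \{0.05, 0.5, 5, 20\}$ is run and the best residual sum of
squares kept; on noiseless curves the first adequate fit short-circuits the
rest. Degenerate inputs (constant series, missing autumn limb, reversed
midpoints) return a flagged non-converged fit object, never an exception and
never a silently wrong answer.

**Derived metrics.** $\sqrt{\delta}$ is a model-based migration distance (km)
and $2\varphi$ a migration-duration surrogate (days), reported per season for
double fits. For a logistic the elapse between the ¼ and ¾ points is actually
$2\varphi\ln 3 \approx 2.2\varphi$; because conventions differ, the package
exposes both $2\varphi$ and the analytic quantile-crossing times
$t(q) = \theta + \varphi\,\ln\frac{q}{1-q}$ so users can compute any span they
prefer.

**Timing segmentation.** Interactive identification of departure and arrival
points on NSD plots is replaced by a deterministic rule: departure and arrival
are where the fitted limb crosses $f\delta$ and $(1-f)\delta$, by default
$f = 0.025$. The default is a compromise: much smaller $f$ chases the flat
logistic tail (timing becomes hypersensitive to $\varphi$), much larger $f$
clips genuinely travelled days. With the default, recovered spring departures
on synthetic birds sit within ~1 day of the configured migration onset; the
test suite requires 3 days for 90% of 50 seeds. All crossings are analytic,
so the rule is reproducible and its sensitivity to $f$ can be examined
directly.

## Movement metrics

Hourly movement distance uses only steps whose time gap lies in the closed
30–60 minute window (the transmitters' within-burst cadence), dividing the
great-circle step length (R = 6371 km) by the gap in hours; longer gaps say
more about the duty cycle than about flight. Seasonal summaries first average
within animal, then across animals — the animal is the sampling unit, so n is
the number of birds, not the (vastly pseudo-replicated) number of steps — with
normal-approximation 95% CIs across animals. Whether two seasons' CIs overlap
is reported alongside. Observed-vs-model comparisons
(`regress_observed_vs_model()`) are ordinary least squares of the
track-segmentation metric on the model surrogate.

## Seasonal climatic niche overlap

Four climate variables enter the ordination: seasonal mean monthly minimum and
maximum temperature (°C), seasonal mean monthly precipitation (mm), and
seasonal mean wind speed (m/s), looked up at occurrence locations by
nearest raster cell. Occurrence data are the track fixes thinned to one per
calendar day (seeded draw) and labelled by month windows — November–February
for winter, June–August for summer — the periods when a migrant is reliably on
its seasonal range.

The comparison happens in the space of the first two principal components of
the *pooled* climate table (both seasons' backgrounds — every raster cell of
each region — plus both seasons' occurrences, centred and scaled). On a
100×100 grid over the pooled score range (10% margin), Gaussian
product-kernel densities of occurrences ($o$) and background ($e$) are
evaluated at cell centres with Scott's rule bandwidths computed once on the
pooled scores, so both seasons are smoothed identically.

The default occupancy is background-corrected, $z \propto o/e$: it asks how
*selectively* a season's climates are used relative to what was available,
which is what makes niches comparable across regions with different climatic
extents. Two numerical guards matter:

* $e$-threshold: $z$ is set to zero where $e < 0.05\,\max e$. Both kernel
  densities decay like Gaussian tails far from their data, and the ratio of
  two near-zero tails is numerically meaningless — without the threshold,
  spurious far-tail cells can dominate the rescaled occupancy and corrupt both
  overlap indices in either direction. The 5% level confines the ratio to
  cells with non-trivial available environment; the uncorrected mode
  (`correction = FALSE`) remains available for sensitivity analysis.
* Overlap is computed on occupancies renormalised to sum to one over all
  cells; cells where both are zero contribute nothing.

Schoener's $D = 1 - \tfrac12\sum|p_1 - p_2|$ and the Hellinger-based
$I = 1 - \tfrac12\sum(\sqrt{p_1} - \sqrt{p_2})^2$ both live in $[0, 1]$, are 1
exactly when the normalised occupancies coincide and 0 for disjoint supports.
$I \ge D$ is *not* guaranteed in general and is not asserted anywhere; what is
tested instead is that both indices fall monotonically as one niche is
translated away from the other, and that $D$ moves by less than 0.02 when the
grid resolution is doubled. One-dimensional overlap of a single variable
(`variable_overlap_1d()`, used for wind) is the integrated minimum of two
kernel densities on a common grid.

## The synthetic-data generator

The generator encodes the study conditions every test runs under:

* **Trajectories.** True positions follow an hourly Gaussian random walk
  attracted to the active range centre (attraction 0.5/day, within-range step
  scale 8 km/day), with directed movement at 150 km/day toward the other
  centre inside the migration windows (days 110–125 and 270–285). The default
  centres — Gulf coast (−90.5, 30.5) and northern plains (−96.0, 47.5) — are
  ~1950 km apart, inside the 1000–2300 km span of model-based migration
  distances the package is designed around. Within-range motion is
  deliberately a *simple* attraction walk, not a fitted movement model: only
  the NSD plateau structure matters for phenology, and simplicity keeps the
  oracle (plateau NSD = squared centre separation) exact.
* **Duty cycle.** Six consecutive hourly fixes every 48 h from January to
  mid-June and from October onward, and every 10 days mid-June–September —
  the coarse-summer pattern that motivates model-based (rather than purely
  observational) migration metrics in the first place.
* **Argos error.** Each fix draws a class (defaults 10/20/30/40% for
  LC3/LC2/LC1/LC0) and isotropic Gaussian noise with the class SD
  (0.25/0.5/1.5/5 km).
* **Climate fields.** Cell-wise independent Gaussians per region;
  precipitation and the diurnal temperature gap are truncated at zero
  (inverse-CDF truncation), and maximum temperature is minimum plus the gap,
  so physical invariants hold cell-wise by construction. Default means put
  winter and summer temperatures and precipitation ~7–10 SDs apart while wind
  is nearly identical (3.33 ± 0.4 vs 3.26 ± 0.34 m/s) — a textbook niche
  switcher whose wind niche nonetheless overlaps. An `identical_seasons`
  switch draws both regions from the winter distributions, the niche-tracking
  null.

**What the generator does not emulate** — and therefore what passing tests do
not establish about real data: spatial autocorrelation of climate (cells are
independent), land/water masks and habitat selection, multi-year tracks and
between-year phenology variation, transmitter failure and data gaps beyond
the duty cycle, behavioural heterogeneity (staging, exploratory loops), and
non-Gaussian heavy-tailed Argos errors. The validation shows the estimators
are correct under their assumptions and robust to the noise structure
modelled; real-data robustness must be argued separately.

## Problem sizes and reproducibility

Every stochastic routine takes an explicit seed and restores the caller's RNG
state. The test suite uses 20-seed replicate sets for Monte-Carlo properties
(plateau calibration, error reduction), 50 synthetic birds for timing
recovery, 100 replicates for noisy-fit robustness, and occurrence samples of
~1000 per season for the niche separation checks — sizes chosen so each
property is measured well while the whole suite stays quick on a single CPU.
Parameter-recovery checks run at 0.1-day sampling over days 1–250 (single
model) and daily sampling over a full year (double model), matching how the
models are used on real duty-cycled data.

## Known limitations

* The CRW measurement model is isotropic and class-homoscedastic; real Argos
  ellipses are anisotropic.
* The double sigmoid assumes one spring and one autumn transition with a
  common asymptote; multi-stage migrations or non-returning birds need the
  flagged non-convergence path and manual follow-up.
* The background-corrected occupancy depends on the background extent chosen;
  with synthetic rasters the region *is* the background, but on real data the
  choice of accessible area shifts both $D$ and $I$ and should be varied.
* Timing from threshold crossings inherits the fitted model's bias when the
  NSD rise is asymmetric; the threshold fraction is exposed for sensitivity
  analysis.
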