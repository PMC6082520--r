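---
title: "Methods: SCPD demography and MAT climate reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SCPD demography and MAT climate reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palaeodyn)
```

This vignette is the package's own account of the two models it implements,
the assumptions behind them, the tunable parameters and their defaults, and
the choices made where the design was genuinely open. It states no empirical
result that the test suite and `scripts/acceptance.R` do not themselves
compute.

## 1. The demographic model

The working assumption of dates-as-data demography is that the number of
radiocarbon-datable depositional events per calendar year is, on average,
proportional to the intensity of human activity. A single measurement
$x \pm \sigma$ relates to calendar age $\theta$ (in years cal BP, before
AD 1950) through the calibration curve $\mu(\theta)$ with its own error
$\sigma_{curve}(\theta)$:

$$p(\theta) \propto \exp\!\left\{ -\frac{(x - \mu(\theta))^2}
  {2(\sigma^2 + \sigma_{curve}(\theta)^2)} \right\}.$$

`calibrate_date()` evaluates this on a 1-year grid and normalizes it over
the analysis window. The Summed Calibrated Probability Distribution (SCPD)
is the pointwise sum of the per-event densities, so its total mass equals
the event count and local level is read as relative activity.

**Time axis.** Everything internal is cal BP; `bc_to_bp()`/`bp_to_bc()`
convert at the boundary (BP = BC + 1950). Growth models and linear trends
are fitted on the calendar-forward axis $t = 1950 - \text{cal BP}$ so that a
positive rate means growth toward the present.

**Grid and normalization.** The calendar grid step is 1 year — finer than
the 5-year node spacing of reference curves over this period, and cheap at
desk scale; curve values between nodes are interpolated linearly (for both
$\mu$ and $\sigma_{curve}$; the curve error has no published interpolation
convention, and linear matches standard practice). Densities are normalized
over the analysis window rather than the full curve support; windows should
extend several $\sigma$ beyond the span of interest so truncation is
negligible. A date whose unnormalized mass over the window falls below
1e−12 is rejected as incompatible with the window rather than silently
renormalized.

### Pre-screening and pre-analytic binning

`prescreen_dates()` keeps measurements with $\sigma$ strictly below 95 ¹⁴C
years (a compromise between global uncertainty and sample size; stricter
cutoffs of 40–50 years discard reliable if imprecise dates) and with a
context class in the requested set. `combine_contexts()` then enforces one
unit of probability mass per depositional event: same-`(site, context)`
dates are tested with the Ward–Wilson statistic
$T = \sum_i (x_i - \bar x)^2/\sigma_i^2$, $\chi^2_{n-1}$ under the null of a
shared true age. Groups passing at $\alpha$ (default 0.05, configurable —
the acceptance level is a convention, not an inference) are replaced by
their inverse-variance pooled mean
$\bar x = \sum(x_i/\sigma_i^2)/\sum(1/\sigma_i^2)$,
$\bar\sigma = (\sum 1/\sigma_i^2)^{-1/2}$, calibrated once. Groups that fail
are **retained separately and flagged** rather than dropped: combination
software conventionally warns and leaves the decision to the analyst, and
automatic exclusion would silently remove data. Either way the number of
represented events never changes.

### Null models

Two artefact sources are modelled explicitly rather than argued away:

*Taphonomy.* Older contexts survive less often. `taphonomic_null()`
evaluates the published global power-law decay
$n_t = 5.726442\times 10^6\,(t + 2176.4)^{-1.3925309}$ with $t$ in cal BP
(the convention of the original taphonomic study; whether the comparison is
run on a BC or BP axis is not fixed by the method, so the grid is an
argument). An empirical SCPD whose shape tracks this curve can be explained
by preservation alone.

*The calibration curve itself.* `simulate_uniform_scpd()` builds the SCPD
that a perfectly constant deposition rate would produce: for every calendar
year a date with mean $\mu(\theta)$ is calibrated and the results are
summed. Structure in this series — peaks at steep calendar-age steps,
smearing over plateaus — is attributable to the curve, not to people. The
default is deterministic (each date mean set exactly to $\mu(\theta)$,
$\sigma = 25$ ¹⁴C yr, one date per year): the construct is an expectation,
and determinism makes it exactly linear in the per-year date count.
Seeded Gaussian perturbation of the means is available
(`noise = TRUE`) when a sampled rather than expected null is wanted.
`standardize_scpd()` puts the empirical and simulated series on a common
z-score scale for comparison.

### Smoothing, envelope, growth tests

`lowess_smooth()` damps the spurious peaks and troughs that curve slope
induces. The smoother is locally weighted linear regression with tricube
weights and bisquare robustification, with fully documented conventions
(neighbourhood size $r = \max(3, \lfloor \text{frac} \cdot n\rfloor)$;
bandwidth = distance to the $r$-th nearest neighbour; robustness weights
$(1 - (e/6m)^2)^2$ with $m$ the median absolute residual). The smoothing
fraction is not something the original desk workflow pins down, so it is a
parameter; the default `frac = 0.1, iters = 2` spans about a century of a
millennium-long window — wide enough to bridge individual calibration
wiggles, narrow enough to keep century-scale demography. These conventions
are restated independently by the test oracle, which recomputes the smoother
per point through `lm()`.

`bootstrap_envelope()` quantifies how much structure a no-change history
can fake: each of `reps` (default 500) replicates draws the empirical
number of events uniformly over the window, back-maps them through the
curve with measurement errors resampled from the screened dataset's own
error pool (preserving the real error structure), adds measurement noise at
the combined variance $\sigma^2 + \sigma_{curve}^2$ — the same error model
calibration assumes — calibrates, sums, and smooths. The 95% band is the
pointwise 2.5/97.5 order statistic across replicates (so two replicates
give exactly min/max), and identical seeds give identical envelopes.

`fit_logistic()` fits the neutral-growth null
$N(t) = K/(1 + e^{-r(t - t_0)})$ by Levenberg–Marquardt least squares.
Initialization uses $K_0 = \max(y)$, $t_0$ at the half-maximum crossing and
$r_0$ from the local slope there ($r = 4\,\text{slope}/K$ at the
inflection); a deterministic grid of five scaled/shifted restarts guards
against local minima before failure is declared. A constant series is an
acceptable degenerate limit ($r \to 0$, $K \to 2c$, rss $\approx 0$).
`linear_trend()` provides the straight-line baseline, and
`detect_excursions()` reports maximal runs of at least `min_run` years
(default 30, suppressing single-cell noise) strictly above/below a baseline
or outside an envelope.

## 2. The climate model

The Modern Analogue Technique assumes compositionally similar pollen
assemblages come from similar vegetation, hence similar climates. The
package reconstructs two variables: mean summer (JJA) temperature and total
summer precipitation.

**Filters** (`filter_modern()`): geolocation error larger than 5 km,
recorded-vs-DEM elevation difference larger than 250 m (both strict
inequalities, so boundary values are retained), riverine/estuarine contexts
(waterborne long-distance pollen), and terrestrial counts below 400 grains
are rejected; the rejection log records each sample's first failing rule in
the order geolocation → elevation → context → count. Missing geolocation
error or DEM elevation passes with a log entry — unknown metadata should
not silently empty a training set. The 400-grain floor applies to modern
samples only; fossil counts are often smaller and are not thresholded.

**PFT aggregation** (`pft_proportions()`): percentages are taken over the
terrestrial sum only, then aggregated into plant functional types and
renormalized. PFTs reduce dependence on taxon-specific analogues and damp
anthropogenic disturbance of individual taxa. Terrestrial taxa missing from
the mapping are excluded with a warning (configurable to an error).

**Analogue matching** (`mat_reconstruct()`): dissimilarity is the Squared
Chord Distance $\sum_i (\sqrt{p_i} - \sqrt{q_i})^2$, bounded by 2, chosen
for its discrimination between vegetation types. The reconstruction is the
weighted mean of the $k = 9$ closest training samples. The weighting kernel
is not pinned down by the desk workflow ("weighted average"), so it is a
documented convention: $w_i \propto 1/\text{SCD}_i$ with distances floored
at $10^{-6}$; distances at or below the floor take all the mass (split
equally), so an exact analogue returns its own climate exactly. Ties at the
$k$-th distance break by training order, for determinism. Alternatives
(equal weights, $1/\text{SCD}^2$) are a parameter. Whether $k$ was fixed a
priori or re-tuned per variable is ambiguous in the source workflow; here
$k$ is a per-call parameter with default 9.

**Cross-validation** (`mat_cross_validate()`): leave-one-out, or h-block
where every training sample within $h = 100$ km (great-circle, Earth radius
6371 km) of the test sample is also removed — the defence against spatial
autocorrelation, with $h$ chosen so pollen source areas of test and
analogue do not overlap. $r^2$ is the squared Pearson correlation of
predictions against observations (the transfer-function convention) and
RMSEP the root mean squared prediction error; skill is judged by RMSEP
falling below the 1σ of the observed climate. Samples whose pool is
depleted below $k$ are flagged, excluded from the summary, and warned
about.

## 3. Regional synthesis

`age_model()` implements the classical linear-interpolation age-depth model
(control ages taken as weighted means of calibrated densities, the
classical point estimate); dating errors interpolate linearly between
controls, extrapolation beyond the outermost controls is off by default,
and age reversals are rejected naming the offending pair. The 1000-yr
dating-distance mask (`dating_distance()`) is measured in modelled age, not
depth (the workflow states the cutoff in years).

`to_anomalies()` subtracts, per variable, the mean of all reconstructions
inside the reference window (default 3750–2750 cal BP, i.e. 1800–800 BC),
pooled per region. Pooling per region rather than per site is the reading
adopted for "mean of all reconstructions within each region"; per-site
centring is available by passing `group = "site"`.

`window_average()` bins per-sample reconstructions into 100-yr windows
every 50 yr. Membership is half-open $[c - 50, c + 50)$ so a sample on an
overlap boundary counts once. A window's weight is the inverse of its
members' mean interpolated dating error, capped at 10× the series median so
an exact control-point hit cannot dominate the fit; empty or
dating-distance-masked windows carry `quality = FALSE` and never reach the
regression.

`regional_loess()` pools the unmasked windows of all sites in a region and
fits a degree-1 LOESS of anomaly on window centre with the dating weights
as observation weights (span 0.06 of the pooled points). With small
synthetic datasets the span is floored so each local fit spans at least 4
distinct window centres — several sites share the same centres, and
distinct abscissae keep the local linear fits well-conditioned. The 95%
band is parametric, fitted ± 1.96 pointwise standard errors; the source
workflow does not specify its band construction further, and a parametric
band is the cheapest defensible choice.

## 4. The synthetic-data generators

The generators exist so that every stage has inputs with known ground
truth:

- `make_calibration_curve()` builds piecewise-linear curves from contiguous
  slope segments (slope 0 = plateau, steep slope = calendar-age step,
  continuity by construction, constant error). This reproduces the curve
  *features* that distort calibration; it does not emulate real decadal
  wiggle structure, so tests against these curves say nothing about
  wiggle-matching behaviour.
- `simulate_dates()` draws context ages from a named event density
  (uniform, logistic, piecewise, Gaussian mixture) by inverse-CDF on the
  yearly grid, then draws measurement means at the combined variance
  $\sigma^2 + \sigma_{curve}^2$ — keeping simulation and inference
  consistent. Site/region assignment is round-robin; no spatial realism is
  attempted.
- `make_training_set()` and `make_fossil_core()` use Gaussian taxon
  responses over the (temperature, precipitation) plane with multinomial
  counting noise. In the example community (`example_response_spec()`) the
  two member taxa of each PFT share similar optima — PFTs are ecologically
  coherent groups, and aggregation must preserve the climate signal —
  while PFT-level optima are spread over the plane so both variables stay
  identifiable. Coordinates are placed on a lattice honouring a minimum
  pairwise distance (for h-block experiments); `climate_field = "gradient"`
  makes climate a smooth function of the coordinates, producing the spatial
  autocorrelation that h-block validation exists to defeat.
- `inject_metadata_faults()` corrupts disjoint samples against a fault
  plan and returns the truth log, exercising the modern-sample filters.

Passing tests on these generators demonstrate correctness of the machinery
under the stated error models; they do not demonstrate that real pollen
responds Gaussianly, that real deposition is Poisson-like, or that real
calibration curves are piecewise linear.

## 5. End-to-end experiment and problem sizes

`ramp_recovery_replicate()` runs the full fossil workflow against a known
history — summer temperature falling linearly by 2 °C across the
3750–2750 cal BP window, precipitation constant — with three synthetic
cores (65 samples each, 10 yr/cm, five noisy dated controls at 1σ = 40 yr)
and a fresh 150-sample training set per replicate. The replicate statistic
is the fitted start-minus-end difference of the regional temperature curve;
truth is +2 °C. The acceptance script runs 50 seeded replicates and reports
the fraction recovering the correct sign within 50% of the magnitude.

Problem sizes used throughout (chosen as the package's own test scale): the
bootstrap envelope runs at the study scale of 852 events × 500 replicates
over a 1001-year window; Monte-Carlo checks of the Ward–Wilson size use
10⁴ pairs; MAT skill is assessed on 300-sample training sets; growth-sign
recovery uses 100 replicates of 500 contexts. The full test suite and the
acceptance script each complete in a few minutes on a single core.

## 6. Known limitations

- No Bayesian sequence/phase modelling, reservoir corrections or post-bomb
  curves; calibration is the standard single-date likelihood.
- Only classical linear-interpolation age models (no spline or Bayesian
  accumulation models); control-age uncertainty enters as interpolated 1σ,
  not as full densities.
- No formal changepoint or cross-correlation testing between regional
  curves — excursions are read against baselines and envelopes, as in the
  desk workflow this package systematizes.
- The MAT weighting kernel and tie policy are conventions (documented
  above), not inferences about any particular historical software's
  internals.
- Anomaly centring assumes the reference window is well covered by
  reconstructions; sites dated entirely outside it are an error by design.
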