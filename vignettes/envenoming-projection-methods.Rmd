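---
title: "Methods: a mechanistic snakebite envenoming model under global change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a mechanistic snakebite envenoming model under global change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(envenomr)
```

## The model

envenomr implements a mechanistic model of snakebite envenoming incidence
in which bites arise from a mass-action contact process between humans and
venomous snakes. For spatial unit $i$ in year $t$,

$$
\Delta He_i \;=\; H_{i,t}\,
\bigl(1 - e^{-h_i}\bigr)\, P_{env,i},
\qquad
h_i = \max\!\bigl(0,\; \beta_i \textstyle\sum_{s=1}^{7} c_s S_{s,i} + \rho_i\bigr),
$$

where $\Delta He_i$ is the expected number of new envenoming cases,
$H_{i,t}$ the susceptible population, $S_{s,i} \ge 0$ an abundance *index*
for snake species $s$ (seven medically relevant taxa), $c_s \ge 0$ a
species-specific contact rate, and $\rho$ an intrinsic conditional
autoregressive (CAR) random effect on the rook-adjacency lattice. The
human–snake contact rate is log-linear in baseline population density with
land-cover-class-specific terms,

$$
\beta_i = \exp\bigl(\beta_{0,L_i} + \beta_{1,L_i}\log(1 + H^{2010}_i)\bigr),
$$

over the five-class legend (forest, degraded forest, agriculture, urban,
tea plantation), and the probability that a bite envenoms is logit-linear
in land cover and species abundances,

$$
\operatorname{logit} P_{env,i} = B_0 + B_{L_i} + \textstyle\sum_s b_s S_{s,i}.
$$

With five classes and seven species the bite submodel has
$2\cdot 5 + 7 = 17$ free parameters and the envenoming submodel
$1 + 5 + 7 = 13$. Observed counts are Poisson with mean $\Delta He$
(a binomial observation model would be natural too; Poisson is the
package default because annual incidence is far below the population).

Design choices where the functional form was open:

* **$\beta$ functional form.** A log-linear contact rate in
  $\log(1+\text{density})$ with class-specific intercept *and* slope is
  the simplest form that is a function of both land cover and baseline
  population and yields exactly 17 bite-submodel parameters.
* **Placement of $\rho$.** The CAR effect is added inside the hazard,
  $h = \beta\sum c_s S_s + \rho$, floored at zero so the hazard cannot go
  negative. Adding it outside the exponential (to the log-hazard) would be
  an alternative; the floored additive form keeps the hazard scale
  interpretable and makes $p_{bite}\in[0,1)$ automatic.
* **CAR flavour.** Intrinsic CAR with a sum-to-zero constraint;
  `car_log_density()` is the standard pairwise-difference form with the
  rank-deficient $(n-1)/2\,\log\tau$ normaliser.

## Inference

`fit_mcmc()` is an adaptive random-walk Metropolis-within-Gibbs sampler:

* single-site updates for the 30 fixed effects, adapting each step size
  towards an acceptance rate of 0.35 during warmup (the first half of the
  chain);
* single-site updates of $\rho$, performed as two vectorised sweeps over
  the two colour classes of the bipartite rook lattice (within a colour,
  sites are conditionally independent given the other colour, so per-site
  accept/reject decisions can be made simultaneously), re-centred to the
  sum-to-zero constraint after each scan;
* a Gibbs draw for $\tau$ (Gamma conjugacy given the pairwise quadratic
  form of $\rho$);
* three "ridge" moves along the weakly identified directions of the
  posterior: a joint shift of $B_0$ against all $B_L$ (the envenoming
  intercept is only softly identified against the class coefficients); a
  joint rescaling of all $c_s$ against the $\beta_0$ intercepts (only the
  product $\beta \sum c_s S_s$ is likelihood-identified); and a per-class
  joint move of $(\beta_{0,L}, \beta_{1,L})$ along their correlation
  direction. The first two leave the likelihood exactly invariant and are
  accepted on the prior ratio (plus a Jacobian for the rescaling); they
  are what makes the soft ridges mix.

Priors follow weakly informative defaults: Normal(0, 10²) on all fixed
effects on their linear scales, half-Normal(0, 5) on the non-negative
$c_s$, Gamma(1, 0.01) on $\tau$. Diagnostics are split-$\widehat R$ and a
Geyer initial-positive-sequence effective sample size; model fit is
summarised by DIC ($\bar D + p_D$). The plug-in deviance is focused on
the expected incidence — $p_D = \bar D - D(\bar\mu)$ with $\bar\mu$ the
posterior mean of $\Delta He$ — because evaluating the deviance at the
posterior-mean *parameters* can hit the hazard floor (a zero mean against
a positive count, hence an infinite deviance), whereas every accepted
state has $\mu > 0$ wherever $y > 0$, so $\bar\mu$ does too.

The posterior predictive check is a Pearson correlation between observed
counts and the posterior-median $\Delta He$, with a Monte Carlo p-value
whose null preserves spatial autocorrelation: the observed field is
rotated by random row/column shifts on the lattice torus and the
correlation recomputed for each rotation.

**Identifiability and the recovery experiment.** Because only
$\beta\sum c_s S_s$ is likelihood-identified, the scale split between
$e^{\beta_0}$ and the $c_s$ is set by the priors. The synthetic truth in
`default_params()` therefore uses prior-consistent scales
($c_s = O(1\!-\!3)$, $\beta_0 \approx -4$): a recovery experiment whose
truth sits deep in a low-prior-volume direction would fail interval
coverage for any correct sampler, which is a statement about the design,
not the inference. Interval coverage is assessed on the 30 fixed effects;
$\tau$ is confounded with the hazard level through the floored $\rho$ and
is typically overestimated, which we accept and do not test.

## The synthetic study system

All inputs are generated on a regular lattice (default 20 × 20 cells of
1 km, so 5 × 5 block upscaling gives a 4 × 4 coarse grid) from one master
seed, split deterministically into per-stage streams (`derive_seed()`).

* **Climate** (`gen_climate()`): monthly minimum/maximum temperature and
  total rainfall. The spatial pattern is a *fixed* climatology — an
  elevation-like north–south gradient plus one smoothed Gaussian field per
  stack — with a seasonal cycle, small national interannual anomalies
  (defaults: 0.01 °C for temperature, 1% for log-rainfall) and the linear
  scenario trend. `tmin ≤ tmax` and `rain ≥ 0` hold by construction. The
  interannual defaults are deliberately small: the abundance layer
  responds exponentially to climate, so the synthetic system is more
  climate-sensitive than a real one, and a smooth null climatology is what
  keeps a no-trend scenario flat (the null-calibration property below).
  Experiments that need year-to-year spatial contrast (the climate-window
  re-analysis) pass `annual_field_sd > 0` to add spatially structured
  annual anomaly fields.
* **Land cover** (`gen_landcover()`): a smoothed Gaussian field cut at the
  empirical quantiles that realise the requested five-class shares
  exactly up to rounding, giving spatially clumped mosaics.
* **Population** (`gen_population()`): a smoothed log-normal 2010 surface
  propagated decadally to 2050. Only the growth *increment* is
  redistributed towards urban proximity, so growth multipliers of 1 leave
  the layer untouched and national totals follow the multipliers exactly.
* **Species truth** (`gen_species_truth()`): log-linear abundance indices
  in standardised bioclim summaries, land-cover covariates (neighbourhood
  agriculture proportion, distance to forest, tree-cover proportion) and
  the distance to a per-species climatic niche centroid, with occurrence
  points drawn multinomially (150 per species by default) with
  probability proportional to intensity. Niche centroids sit near or
  below the baseline climate mean: the species are locally adapted, so
  sustained warming increases niche distance and degrades suitability for
  most taxa — the mechanism that drives declining incidence in the warming
  scenarios.
* **Counts** (`simulate_incidence()`): Poisson draws around the forward
  model's $\Delta He$, capped at the population. The observation noise
  model is a package choice, not asserted of any survey.

What the generator does *not* emulate: realistic coastlines or geography,
survey design effects (imperfect detection, clustered reporting),
species interactions, and the area-interaction structure of real
point-process fits (the abundance stand-in is an inhomogeneous log-linear
intensity; the projection pipeline consumes only an intensity surface).
Passing tests therefore demonstrate internal consistency and correctness
of the algorithms, not transferability to real surveillance data.

## Global-change components

* **Delta-method bias correction.** Difference corrections
  (observed − modelled reference climatology, used for temperatures) add;
  ratio corrections (observed / modelled, used for rainfall and other
  ratio-scale variables, denominator floored at 0.01 to guard dry cells)
  multiply. Corrections are per calendar month and cell. Applying the
  correction back to the modelled reference reproduces the observed
  climatology (exactly for differences, up to the floor for ratios);
  `validate_downscale()` reports Pearson r, OLS slope/intercept and RMSE
  of observed on backcast.
* **Climate window.** Snake abundance is projected from the mean climate
  of each year and its two predecessors (window 3).
  `select_climate_window()` re-derives this choice: it fits one Poisson
  regression of counts on the three bioclim summaries (log-population
  offset) per candidate window 1–10 and minimises AIC, ties toward the
  smaller window. AIC is our choice of criterion; the model-comparison
  statistic behind the original re-analysis is not stated.
* **Land cover change.** A CLUE-style competitive allocator:
  score(cell, class) = logit suitability (per-class logistic regressions
  of presence on drivers) + a conversion-elasticity bonus for keeping the
  current class + a per-class offset. Cells take their best legal class;
  offsets adjust iteratively (steps shrink on oscillation) until counts
  match demand, and an exact repair pass (cheapest legal reassignments,
  then profitable pairwise-swap and 3-cycle polishing) enforces demand to
  tolerance 0 when asked. Non-convergence errors are reserved for demand
  that is infeasible under the transition rules. On maps small enough to
  enumerate, the result attains the exhaustive-search optimum of total
  score subject to demand. Tie-breaks go to the lowest legend index;
  runs are deterministic. Annual pairwise change caps are exposed
  as transition rules but default to fully permissive.
* **Tree cover.** Five 20%-band categories map to midpoints (0.10, 0.30,
  0.50, 0.70, 0.90), rescaled by one factor so the study-area mean equals
  a reference proportion, clamped to [0, 0.99].
* **Population projection.** Cellwise bias factors are the mean
  observed/predicted quotient over overlapping years (cells with
  predicted density below 0.5 persons/km² take the study-area mean
  factor), applied to every decadal layer, then interpolated annually by
  shape-preserving piecewise-cubic Hermite interpolation (PCHIP,
  Fritsch–Carlson slopes: weighted-harmonic interior slopes, zero at
  local extrema, clipped three-point end slopes). Knots are interpolated
  exactly, monotone segments stay monotone, and non-negative knots give
  non-negative years. The implementation is authored in the package and
  cross-checked in the tests against an independent PCHIP implementation.

## Scenario projection

`run_scenario()` drives one SSP × RCP × RCM projection 2010–2050:
generate (or delta-correct) the scenario climate; refresh logistic
suitability from dynamic climate and population drivers and allocate land
cover annually along the scenario demand trajectory; bias-correct and
PCHIP-interpolate population; project the seven abundance indices from
the 3-year rolling climate mean and the year's land-cover covariates;
upscale; and evaluate $\Delta He$ with the fitted parameters held
constant. Scenario pairings follow the design: SSP1 with no further
emissions and the historical trend; SSP2 with RCP4.5; SSP5 with RCP8.5;
RCP scenarios nest three synthetic regional circulation models differing
in bias (removed by the delta correction) and trend strength. Default
demand trajectories are linear; population growth is highest under SSP2,
then SSP1, lowest under SSP5.

Upscaling follows two rules. Extensive quantities aggregate by block
sums (`upscale_sum()`, exactly conservative); land cover by majority vote
with ties to the lowest legend index (`upscale_majority()`). Because the
model is fitted at the fine (per-km²) scale, the layers that feed the
fitted coefficients — species indices and the baseline contact-rate
density — enter the coarse forward evaluation as block sums divided by
block area (i.e. aggregated to the fitted units), while the susceptible
population enters as the block total so that incidence is a case count.
The CAR field is held fixed and enters as its block mean.

Change statistics: per-cell OLS slopes of incidence on year
(`pixel_trend()`); percentage change 2010→2050 with zero-baseline cells
masked (`pct_change()`); the national series as total incidence over
total population regressed on year, with accumulated percentage change
relative to the fitted 2010 value and a standard error propagated from
the slope's OLS standard error (`national_series()`); RCM consensus as
the per-cell count of strictly negative slopes (zero counts as
not-decreasing) with area fractions (`rcm_consensus()`); the dominant
species per cell as the argmax of $c_s S_s e^{b_s}$ (a pure-$c_s$
weighting is available, since the exact weighting of the original figure
is not printed); and per-transition summaries of percentage change
(median, IQR, 2.5/97.5 percentiles) over observed (from, to) class pairs.

## Calibration properties and problem sizes

The test suite asserts, among others: a null scenario (no trends,
constant demand, unit growth) keeps the accumulated national change
within ±1% over 41 years; a warming scenario constructed so niche
distances grow for negative-coefficient species produces a negative
national trend; the window re-analysis recovers window 3 in at least
8/10 seeded replicates; and a recovery experiment (20 × 20 lattice,
3 chains × 20,000 iterations, ~2 minutes) covers at least 70% of the 30
fixed-effect truths with 90% intervals, with median split-$\widehat R$
below 1.1 and posterior-predictive r above 0.8. These problem sizes were
chosen to keep a full check run at desk scale while leaving the
statistical properties testable.

## Known limitations

* The CAR re-centring after each scan is the standard constrained-ICAR
  practice but is an approximation when the hazard floor binds.
* $\tau$ and the hazard level are partially confounded; $\tau$ is
  typically overestimated and is excluded from coverage claims.
* The allocator is a CLUE-style mechanism, not a re-implementation of any
  specific external tool; demand interacts with suitability only through
  the offsets and elasticity.
* Scenario projections extrapolate the abundance regressions outside the
  fitted climate range; collinearity between raw bioclim covariates and
  niche distance makes per-seed extrapolations noisy unless the niche
  signal dominates (the directional experiments are constructed that
  way).
* Expert relative-abundance adjustment is exposed as raw multiplicative
  weights (`apply_expert_weights()`), defaulting to 1.
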