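---
title: "Growth-lifespan trade-offs and stochastic forest demography: methods"
author: "ringlife"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-lifespan trade-offs and stochastic forest demography: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringlife)
```

## The scientific problem

Trees that grow fast when young tend to die younger. If warming (or CO2, or
nitrogen) stimulates tree growth, this growth-lifespan trade-off implies that
today's enhanced forest carbon uptake is partly a loan: faster-growing trees
reach their maximum size - and the mortality risks attached to it - sooner, so
stand biomass gains should be transient rather than permanent. `ringlife`
provides the full chain needed to quantify this from tree-ring data:

1. **ring_io** - read/screen ring-width series (Tucson RWL and a long CSV
   dialect), merge duplicate cores, derive per-tree summaries;
2. **tradeoff** - estimate the trade-off by exponential quantile regression,
   with resampling diagnostics for sample-size and big-tree sampling biases,
   stratified and major-axis fits for environmental confounding, and the
   age-dependent temperature sensitivity of growth;
3. **mortality** - infer size- and age-dependent annual hazards from
   steady-state stand structure and fit parametric hazard models;
4. **stand_simulator** - a 600-year annually seeded stochastic cohort
   simulator with a warming growth stimulus;
5. **synthetic_data** - a generator with known trade-off, noise and mortality
   structure so that every stage is testable without any external download.

The exported functions, `run_pipeline()` and this vignette are the package's
interface; a thin script (`inst/scripts/ringlife.R`) wraps the pipeline for
shell use.

## The trade-off model

For each tree, early growth is the mean ring width over the first ten rings
(`rw_early`, mm/yr) and age `A` is the ring count. Lifespan conditional on
early growth is defined as the 95th quantile of age:

$$\log A_{(q)} = a + b \cdot \overline{RW}, \qquad
  \text{Lifespan} \approx e^{a + b\,\overline{RW}},$$

with `b < 0` the exponential decay constant of lifespan in early growth.
`fit_quantile_exponential()` minimises the pinball (check) loss exactly with a
vertex-exchange algorithm: the optimum of this two-parameter linear program is
a line through two data points; rotating the line about one of its defining
points is a one-dimensional weighted-quantile problem solved in O(n log n),
and a step is accepted only when the loss strictly decreases, so the loop
terminates at the global optimum. The solver is validated in the tests against
an exhaustive search over all pairwise lines (exact agreement for n up to 12;
ties broken by smaller |slope|). Significance of `b` uses a seeded case
bootstrap (default 1000 replicates) because rank-based standard errors are
unreliable at extreme quantiles; the p-value is two-sided with an add-one
correction. Percentiles throughout the package use the type-7
(linear-interpolation) definition, which matters for integer ages.

Cross-species comparisons first rescale each tree by its species maxima
(`normalize_relative()`), and species means are weighted by the cube root of
sample size (`weighted_mean_decay()`) so huge datasets do not dominate.
Symmetric climate relationships (site growth or lifespan against temperature)
use major axis regression (`fit_major_axis()`), the first principal axis of
the covariance matrix, because neither variable is a controlled predictor.

### Screening rules and their boundary semantics

Sites need at least 20 trees and an age coefficient of variation of at least
10% (sample sd; strictly lower is excluded) - even-aged stands cannot reveal
maximum lifespans. Species-level analyses need >= 30 trees; within-species
fits need strictly more than 150 trees from >= 3 sites; archive (ITRDB-style)
sources additionally need >= 3 sites with >= 20 records and >= 100 series.
Archive series whose outermost ring predates AD 1900 (strictly) are classified
dead. Duplicate cores are merged when IDs agree up to the last character
(trailing separators stripped); the per-age mean is used because the source
archives do not state a combination rule (configurable to "first").
Diameter is twice the cumulative ring width, with no bark or pith-offset
correction: problematic trees are meant to be excluded, not corrected.

## Mortality from stand structure

Assuming the stand's diameter distribution N(D) is stationary, the annual
mortality in a 2-cm class is the surplus of trees growing into it over trees
growing out of it, per standing tree:

$$\mu(D) = \frac{I(D) - L(D)}{N(D)}.$$

Two parametric hazards are supported, interpreted as annual death
probabilities (Bernoulli per tree-year, capped at 1):

* diameter-dependent: $\mu(D) = b + k (D - D_0)^4$ above $D_0$, zero at or
  below it. Published defaults `b = 0.025`, `k = 3e-11`, `D0 = 91` mm (the
  minimum coring diameter of the Quebec inventory protocol, below which
  sampled trees are survivors by construction);
* age-dependent: $\mu(A) = a + s A$ above $A_0 = 74$ yr (the age at which the
  average tree reaches 91 mm), defaults `a = 0.021`, `s = 1.5e-6`. This model
  produces no growth-lifespan trade-off and stands in for vegetation models
  without one.

`fit_hazard_model()` refits either form by N-weighted least squares with the
threshold fixed by the sampling design - both forms are then linear in their
parameters, so noiseless bins are recovered exactly. The quartic term is
ill-conditioned against binned, noisy rates: the package's round-trip test
(simulate a stationary stand, estimate per-bin rates, refit) requires `b`
within 0.005/yr but only a factor of two on `k`.

## The cohort simulator

`run_simulation()` seeds a cohort of trees every year for 600 years; each
member is a trajectory drawn with replacement from the extended trajectory
set. Short series are first extended to age 500 (`extend_trajectories()`)
using the mean growth of the 10 oldest trees in the same of six equal-width
early-growth classes, donors dropping out age-by-age. Every year a living
tree grows its trajectory's next ring, updates its diameter, and faces the
hazard evaluated after that year's growth (the order is a documented choice).

The warming stimulus multiplies ring width by
$e^{\lambda(A)\,\delta T(t)}$, where $\delta T$ ramps at 0.0221 degC/yr for 50
years from year 300 and is constant afterwards, and the sensitivity declines
with age: $\lambda(A) = 1.32\times10^{-5}A^2 - 2.91\times10^{-3}A + 0.229$
below 135 yr and 0.07 beyond. `estimate_lambda()` recovers this function from
ring data along a site temperature gradient (10-yr age bands, log ring width
regressed on site temperature per band). Stimulated growth feeds back into
the diameter the hazard sees - that feedback is the trade-off mechanism.

Numerical choices:

* **Death lottery coupling.** One uniform is drawn per tree at seeding and
  the tree dies in the first year its cumulative survival probability drops
  below it. This is distributionally identical to an independent Bernoulli
  per tree-year, but makes paired runs share cohort compositions and death
  quantiles: a run without stimulus is bit-identical to its baseline, and
  under age-dependent mortality a stimulated run has *exactly* the same death
  ages as its baseline, isolating the trade-off mechanism.
* **Age cap.** Trees reaching the trajectory limit (500 yr) die
  deterministically; under both default hazards almost no tree survives that
  long.
* **Smoothing.** Raw annual series are stored; comparisons
  (`compare_scenarios()`) use a 10-year centred moving average (window
  configurable).
* **Mortality-response lag.** A natural detection rule - the change exceeding
  twice its own pre-onset sd - degenerates under paired seeding because the
  pre-onset change is identically zero, so the noise floor is instead the
  pre-onset coefficient of variation of the *baseline's* smoothed death rate.
* **Desk scale.** The default cohort size is 125 trees/yr; the full-scale
  run (1250/yr) is one argument away. Tests and the acceptance script use
  125 so the whole suite runs in a few minutes on one CPU; the simulated
  percent-change quantities are intensive and insensitive to cohort size
  beyond Monte-Carlo noise.

## The synthetic-data generator

`generate_population()` emulates boreal black-spruce-like ring data. Each
tree follows $D(A) = D_{max}(1 - e^{-rA})$: the saturating-exponential family
makes maximum size a trait *independent of growth speed*, matching the
observed size plateau (~300 mm regardless of early growth). Defaults, fixed
a priori from the constants above and not revisited:

* `max_diameter_mean = 300` mm, `max_diameter_sd = 15` mm - a tight size
  trait, so that early-growth variation is dominated by growth speed (the
  generator's design property |cor(early growth, Dmax)| < 0.1);
* `growth_rate_meanlog = log(0.0049)` - the median tree crosses the 91 mm
  threshold near age 74, consistent with the hazard thresholds above;
  `growth_rate_sdlog = 0.5` spans realistic early growth (~0.2-2.5 mm/yr);
* multiplicative lognormal AR(1) noise (`ar1 = 0.7`, stationary sd 0.3) -
  growth is strongly autocorrelated and widths stay positive;
* site temperature multiplies growth speed (`0.1`/degC), giving the
  space-for-time gradient that `estimate_lambda()` and the stratified fits
  exploit;
* observation ages are uniform between 10 and the age at 99% of maximum
  diameter (capped at 500), so site age structures are uneven by construction.

`generate_known_tradeoff_sample()` provides exact parameter-recovery truth:
with $U \sim \mathrm{Unif}(0,1)$, $\log A = a + b\,\overline{RW} + \log U -
\log q$ has conditional q-quantile exactly $a + b\,\overline{RW}$ (the CDF of
$\log U - \log q$ at 0 is $q$). `generate_stand_distribution()` runs an
annual recruitment / growth / stochastic death model to stationarity (total
count drifting more than 1% per decade at the end is an error) and tallies
N, I and L per 2-cm bin, closing the loop with the mortality estimator.

What the generator does **not** emulate: real juvenile growth. Black-spruce
cores show juvenile rings several times wider than mature rings; the
saturating-exponential family anchored at (300 mm, 74 yr at 91 mm) declines
much more gently (e-folding ~200 yr). Consequences are quantified in the
tests: the simulated population's effective growth sensitivity to the
stimulus is ~0.14/degC rather than the ~0.23/degC implied by a
juvenile-dominated mean, so the simulated mean-growth increase at the end of
the warming ramp is ~16% (observed analogue ~29%, which equals the maximum
single-tree boost $e^{\lambda(0)\cdot 1.105} = 1.29$ the stimulus equations
permit at all) and the peak basal-area gain is ~11% rather than ~20%. The
*qualitative* results - a trade-off that emerges under size-dependent but not
age-dependent mortality, a lagged mortality response, large trees dying ~20
years younger, and basal-area stocks reverting to baseline only when the
trade-off is present - are robust to this, and are what the acceptance tests
assert. Passing tests therefore demonstrate the mechanism and the machinery,
not that the generator is a calibrated model of Quebec spruce.

## Other design decisions

* Temperature classes for stratified fits are half-open 2-degC intervals
  anchored at the data minimum; growth bands are equal-count quartiles.
* Nearby-site pooling (site-level climate fits need >= 30 trees) is greedy:
  the smallest pool merges with its nearest neighbour by great-circle
  distance until all pools are large enough.
* The big-tree bias experiment samples (tree, size-class) observations to
  match a field size-frequency table in 2-cm classes; the "threshold"
  scenario keeps classes fully above the 91 mm coring limit, "top10pct" the
  largest decile. The weakening of the trade-off these cause is a few
  percent - comparable to one resample's Monte-Carlo noise - so directional
  tests average over resampling seeds.
* Global seeds expand to per-stage substreams by fixed small offsets, so each
  pipeline stage is individually reproducible.

## Known limitations

* No competition, recruitment response, or self-thinning in the simulator;
  no covariate-dependent hazards (the size-mortality curve is assumed
  independent of temperature and CO2).
* No crossdating, detrending, pith-offset estimation or chronology building.
* Linear mixed-effects climate models and phylogenetic analyses are out of
  scope; stratified and major-axis fits cover the confounding analysis.
* The RWL writer emits one fixed dialect (8-char IDs); exotic Tucson
  variants (tab-separated, header cards) are not parsed.
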