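# ringlife

Growth–lifespan trade-offs and data-driven forest demography from tree rings.

## What it is for

Fast-growing trees tend to die younger. For forest ecologists and carbon-cycle
modellers this matters because any growth stimulation — warming, CO2,
nitrogen — should then raise mortality with a lag and erode the very biomass
gains it creates. `ringlife` implements the complete analysis chain on
tree-ring data:

* **Ring data I/O and screening** — Tucson (RWL) and long-form CSV readers and
  writers, duplicate-core merging, per-tree summaries (mean early ring width
  `RW`, age `A`, diameter = 2 × cumulative ring width), site screening by
  sample size and age-structure evenness (CV of ages ≥ 10%), species
  eligibility rules, and a strict pre-1900 dead-tree classification.
* **Trade-off estimation** — the lifespan model
  `log A(95th quantile) = a + b · RW`, i.e. `Lifespan ≈ exp(a + b·RW)`,
  fitted by an exact pinball-loss quantile regression (vertex-exchange
  solver, validated against exhaustive search), with case-bootstrap p-values,
  species-relative normalization, cube-root-of-n weighted mean decay
  constants, major-axis climate fits, temperature/growth-band stratified
  fits, and resampling diagnostics for sample size and big-tree selection
  bias.
* **Mortality inference** — per-2-cm-bin annual mortality from steady-state
  stand structure, `mu(D) = (I(D) − L(D)) / N(D)`, and parametric hazards:
  quartic diameter-dependent `mu(D) = b + k (D − D0)^4` above `D0 = 91` mm
  (defaults b = 0.025, k = 3e-11) and linear age-dependent
  `mu(A) = a + s·A` above `A0 = 74` yr.
* **Stochastic cohort simulator** — 600 years of annually seeded cohorts
  drawn from extended ring-width trajectories, an annual death lottery under
  either hazard, and a warming growth stimulus
  `RW_stim(t) = RW(t) · exp(lambda(A) · dT(t))` with an age-declining
  sensitivity `lambda(A)` and a 50-year 0.0221 °C/yr ramp.
* **Synthetic data generator** — populations with a known size plateau
  (~300 mm independent of growth speed), lognormal AR(1) ring noise,
  temperature-modulated growth, and samples whose conditional 95th quantile
  of age is exactly a chosen line, so every estimator has recoverable truth.

## Worked example

```r
library(ringlife)

# synthetic black-spruce-like population, extended trajectories
pop  <- generate_population(synth_config(n_trees = 1500, seed = 1))
traj <- extend_trajectories(pop$rings)

# paired baseline / warming-stimulated runs under size-dependent mortality
sim   <- sim_config(cohort_size = 125, seed = 5)
base  <- run_simulation(traj, sim)
boost <- run_simulation(traj, sim, stimulus_config())

# does the growth-lifespan trade-off emerge from size-dependent mortality?
simulated_tradeoff(base, traj, sampling_year = 600, n_boot = 300, seed = 2)
#> Exponential quantile trade-off fit (q = 0.95, n = 2000)
#>   log(lifespan) = 5.4449 -0.4519 * early growth
#>   lifespan at RW = 1: 147.4 years
#>   bootstrap p-value (b != 0): 0.006645

compare_scenarios(base, boost)
#> Scenario comparison (treatment vs baseline)
#>   growth change at end of ramp (yr 350): +15.9%
#>   peak basal-area gain: +10.5%
#>   max post-ramp lifespan reduction (q75 age at death): 21.9 yr
#>   death-rate rise lag after onset: 41 yr
#>   final basal-area change (last decade): +2.0%
```

Reading the output: stimulated growth raises mean radial growth by ~16% by the
end of the 50-year ramp and standing basal area by ~10%, but the boost pushes
trees to the high-mortality diameters sooner — large trees die ~22 years
younger, the death rate rises with a multi-decade lag, and by year 600 the
basal-area stock is back to within 2% of the unstimulated baseline: the carbon
gain is transient. Re-running with `mortality = mortality_age()` (no
trade-off) yields no significant fitted slope, no mortality response, and a
sustained basal-area gain — the behaviour large-scale vegetation models
assume. The methods vignette (`vignettes/ringlife-methods.Rmd`) documents the
models, defaults and numerical choices.

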