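---
title: "Model-data fusion with a monthly 3-PG forest simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-data fusion with a monthly 3-PG forest simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgfusion)
```

## The model

`pgfusion` implements a stand-level, monthly-time-step simulator in the 3-PG
family ("Physiological Principles Predicting Growth"): a causal chain from
light absorption to allometric stand attributes. Each month:

1. **Light and carbon.** Leaf area index follows foliage biomass through an
   age-dependent specific leaf area; absorbed photosynthetically active
   radiation (half of global shortwave) follows Beer-Lambert,
   $\mathrm{APAR} = \mathrm{PAR}(1 - e^{-k\,\mathrm{LAI}})$. GPP is APAR
   times the canopy quantum efficiency $\alpha_C$ (mol C per mol photons)
   reduced by dimensionless environmental modifiers for temperature, frost
   days, soil nutrition and CO2, and by the combined physiological modifier
   $\varphi = f_{\mathrm{age}} \min(f_{\mathrm{VPD}}, f_{\mathrm{SW}})$ —
   the canonical 3-PG "most-limiting" rule for water. NPP is the fixed
   fraction $Y$ of GPP.
2. **Allocation.** The root fraction decreases with $\varphi$ and soil
   fertility; the foliage:stem ratio is a power law of mean DBH anchored at
   2 cm and 20 cm. The three fractions sum to one identically. Litterfall
   ramps with age from a juvenile to a mature monthly rate; roots turn over
   at a constant monthly rate.
3. **Mortality.** Density-dependent self-thinning: the permitted mean stem
   mass is $w_{sx} = w_{sx1000}(1000/N)^{p}$, Yoda's law with nominal
   $p = 3/2$. When the stand exceeds the boundary, the smallest continuous
   number of dying trees (each carrying fractions $m_f, m_r, m_s$ of the
   mean tree's pools) is removed so that the constraint holds; the root is
   found by a bracketed Newton iteration on the log-transformed constraint,
   accurate to well below $10^{-8}$ trees/ha.
4. **Water.** Canopy conductance is the species maximum scaled by
   $\min(f_{\mathrm{VPD}}, f_{\mathrm{SW}})$, age and CO2 modifiers, and
   canopy closure; transpiration and soil evaporation use the monthly
   Penman-Monteith form with net radiation linear in shortwave over the
   astronomical daylight period; interception is a capped linear function of
   LAI; the soil bucket is clamped to $[0, \mathrm{ASW}_{\max}]$ with the
   overflow drained as runoff. The monthly balance closes exactly and is
   asserted to $10^{-9}$ mm in tests.
5. **Structure.** Mean DBH inverts the stem-mass allometry
   $w_s = a_{ws}\,\mathrm{DBH}^{n_{ws}}$ (kg/tree); height and volume are
   power laws of DBH; basal area is exact geometry. Management events set a
   residual stocking, with removed trees carrying configurable fractions of
   the mean tree's pools.

Deciduous species carry foliage through the dormant season in a "debt" pool:
foliage moves to the debt at the leaf-fall month and is restored at the
leaf-grow month. This keeps the canopy trajectory well defined without
requiring production before leaf-out; dormant months have zero GPP by
construction (no foliage), and root turnover continues.

The unit chain for production is: PAR in MJ m^-2 month^-1, 4.6 mol photons
per MJ PAR, 12 g C per mol C, dry matter = carbon / 0.5, pools in Mg DM/ha.
NPP is reported in Mg C ha^-1 yr^-1 (carbon fraction 0.5) at output only;
the model runs on dry matter throughout.

The simulator exists twice: as documented R operations (`step_month()` and
its stage functions) and as a compiled translation used by
`run_simulation(engine = "cpp")`. A test pins the two trajectories to
1e-10 relative agreement, and a third, deliberately plain re-implementation
of the stage chain in the test helpers serves as an independent oracle.

### Parameters that matter most

| parameter | meaning | unit | default (conifer) |
|---|---|---|---|
| `alpha_c` | canopy quantum efficiency | mol C / mol photons | 0.045 |
| `y` | NPP:GPP ratio | — | 0.47 |
| `t_min,t_opt,t_max` | cardinal temperatures | degC | -2, 15, 32 |
| `coeff_cond` | stomatal VPD sensitivity | mbar^-1 | 0.05 |
| `sw_const,sw_power` | soil-water modifier shape | — | 0.7, 9 |
| `w_sx1000` | max mean stem mass at 1000 trees/ha | kg | 300 |
| `thin_power` | self-thinning slope | — | 1.5 |
| `a_ws,n_ws` | stem-mass allometry | kg, — | 0.077, 2.5 |
| `pfs2,pfs20` | foliage:stem ratio at DBH 2/20 cm | — | 1.0, 0.30 |

VPD is computed from the monthly temperature extremes through the Tetens
saturation curve (half the difference between saturation pressure at the
mean daily maximum and minimum) and enters the modifier in mbar — the
3-PG convention for `coeff_cond`.

## Bayesian calibration

Observations are plot x date x variable records of the eight stand
variables inventory programmes measure: stem, foliage and root biomass,
stem number, mean DBH, basal area, LAI and GPP. The likelihood is a
location-scale Student-t per observation — location the simulator's
prediction, one error scale per variable, degrees of freedom `u` shared
across variables — which makes the fit robust to the outliers real
monitoring data contain. Priors are uniform: literature ranges expanded by
half the range on each side and clipped to the physical domain. The
posterior is sampled with DEzs MCMC (differential evolution with a
past-state archive, snooker updates with probability 0.1, a mode-jumping
$\gamma = 1$ step every 10th generation, and archive appends every 10th
generation; the archive is initialised with 10 d prior draws). Three
independent runs of three internal chains each are pooled for the
Gelman-Rubin diagnostics; convergence is accepted at a multivariate PSRF
of at most 1.1.

The evaluation layer draws parameter vectors from the posterior, reruns the
simulator, and reports pBias, RMSE and NRMSE. These are computed per plot
first and then averaged over plots for each posterior draw — the order
changes the result and is pinned by a hand-worked test. Cross-validation
splits by plot (never by observation row), with the extra plot of an odd
count going to the calibration half.

Design choices where the protocol left room:

- **Error model.** One scale per observed variable and a single shared `u`;
  residuals on the raw scale of each variable, no standardisation beyond
  the per-variable scale and no data-stream weighting. GPP observations
  (the flux plot) enter the same likelihood with their own scale.
- **Reduced calibration for the shipped experiments.** Ten model parameters
  are sampled: `alpha_c`, `sla1`, and the pre-registered identifiable
  subset (`a_ws`, `n_ws`, `pfs2`, `pfs20`, `p_rx`, `p_rn`, `w_sx1000`,
  `thin_power`) — allometry, partitioning and mortality, the groups stand
  observations constrain best. The likelihood's error scales and `u` are
  fixed at the generator's values in these experiments so the sampled
  space stays at ten dimensions; `run_calibration()` itself accepts error
  parameters as additional coordinates.
- **Iteration accounting.** `iterations` counts posterior evaluations per
  run, split across the internal chains (the convention of the R MCMC
  packages this interface follows); the shipped experiments use 60,000 per
  run, i.e. 20,000 generations per chain, with 50% burn-in and thinning to
  at most 10,000 retained samples per chain.
- **Management in the likelihood.** Thinning years that an inventory only
  brackets between visits are drawn once, with the dataset seed, and then
  held fixed, so the likelihood is deterministic in the parameters.
- **Initialisation.** Each plot's state is initialised from its first
  visit, which therefore does not enter the likelihood. Two sources are
  supported: the noisy first-visit *observations* (the field protocol, and
  the default) or the noise-free first-visit *truth* the generator retains.
  The distinction matters for parameter recovery: with noisy initial
  states the inference model is misspecified (the simulator starts from a
  wrong state while the likelihood attributes all error to observation
  noise), and the tightly concentrated posteriors acquire a visible bias —
  an errors-in-variables effect, not a sampler defect. The shipped
  recovery and convergence experiments therefore initialise from the
  truth, which keeps recovery well posed; the observation-initialised
  variant remains available to study exactly that initial-condition
  sensitivity.

## The synthetic monitoring campaign

The generator emulates the structure of a national forest inventory (NFI:
~decadal revisits, management year unknown, drawn uniformly strictly
between consecutive visits), an experimental forest management network
(EFM: 5-12-year revisits, management at measurement years), and one
intensive plot (LWF/flux style: 3-5-year revisits, additionally observing
LAI and trailing-annual GPP). Every plot has at least two visits. Noise is
location-scale Student-t with 5 degrees of freedom and scales of 5% of each
variable's network-wide mean — the same family the likelihood assumes, so
parameter recovery is a well-posed experiment.

Climate is intentionally stylised: sinusoidal seasonal cycles in
temperature, precipitation and radiation; a linear 5.5 degC/km lapse rate;
lognormal precipitation noise; frost days from a logistic function of the
monthly minimum temperature. Extreme years are injected by an additive
temperature anomaly (in units of the monthly temperature SD) and a
multiplicative precipitation anomaly (in units of the precipitation CV).
What this emulates — and what it does not: the generator induces the
elevation-dependent limitation regimes the analysis probes (temperature
limitation at the cold end, water limitation at the warm, drier end), but
it has no weather autocorrelation, no orographic structure beyond the lapse
rate, no covariance between radiation and rainfall, and no measurement
protocol artefacts beyond heavy-tailed noise. Passing tests therefore
demonstrate internal consistency of the method, not skill on real data.

## Regional analysis

The regional protocol mirrors a paired-period design: a synthetic habitat
grid (smoothed random elevation field, habitat = an elevation band), and
per cell (i) a reference climatology (month-wise means over the reference
period, frost days rounded), (ii) spin-up from a 2-year-old plantation at
10,000 trees/ha to age 40, thinned at ages 20 and 35 (defaults 2400 and
1050 residual trees/ha, chosen to land near 1,000 at age 40), (iii) 28-30
year runs under reference and scenario forcing from the common age-40
state, keeping ages 41-70 only (early stand development is excluded), and
(iv) per-year NPP anomalies in percent of the cell's reference-period mean.
Summary statistics are the OLS slope of period-mean NPP per cell on
elevation in km (cell means, not pooled cell-years), and the fraction of
habitat cells with an anomaly strictly below a threshold (default -25%).

Climate years classify into warm/cold x dry/wet quadrants by standardised
growing-season (April-October) anomalies against the reference-period
distribution, with |z| >= 1.5 defining "extreme" and ties on the
precipitation axis labelled dry. The annual NPP year is the calendar year;
deciduous dormant months contribute zero.

## Numerical choices and degenerate inputs

- Monthly water fluxes are capped by available water (soil store plus net
  rainfall); any residual clip below zero is reported so the balance closes
  identically.
- Negative Penman-Monteith rates (energy-limited winter months) floor at
  zero.
- An empty stand (`n_trees = 0`) has well-defined all-zero attributes; a
  residual stocking above the current stocking is a no-op with a warning.
- The thinning solver brackets in $[0.05N, N]$ and stops at $10^{-11}$
  trees/ha; a stand so overstocked that no admissible removal satisfies the
  boundary raises a diagnostic error, which the calibration maps to a
  log-posterior of $-\infty$.
- Spin-up cells whose stand collapses are flagged and excluded from the
  regional summaries.
- All stochastic entry points take explicit seeds and restore the caller's
  RNG state; identical inputs give bit-identical outputs everywhere.

## Problem sizes of the shipped experiments

The packaged experiments are sized for a single CPU: a 20-plot network for
calibration (three runs of three chains, 20,000 generations per chain), 200
posterior-predictive draws in the evaluation script (the full protocol uses
1,000, which the functions default to), and a ~300-cell habitat grid for
the regional analysis. These sizes were chosen so the entire pipeline —
data generation, calibration, evaluation, regional analysis — reruns from
scratch in well under an hour while leaving the statistical conclusions
(convergence, recovery, anomaly signs) unchanged; all of them scale up by
changing one argument.

## Known limitations

- Monocultures only: no mixed stands, no between-cohort light competition.
- No stress-based (growth-efficiency) background mortality — only the
  self-thinning law; non-density deaths in data are treated as management
  events.
- The NPP:GPP ratio is constant, a known structural simplification of this
  model family.
- Soil evaporation uses a minimal energy-consistent form (Penman-Monteith
  with a fixed soil surface conductance attenuated by canopy shading),
  isolated behind one operation.
- Height and volume use plain power laws of DBH (the competition-augmented
  variants are out of scope).
- The climate generator's realism limits are listed above; regional
  magnitudes are not comparable to any real landscape, only the qualitative
  elevation and extreme-year patterns are.
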