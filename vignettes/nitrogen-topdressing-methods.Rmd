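---
title: "Methods: crop-model data assimilation for nitrogen topdressing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: crop-model data assimilation for nitrogen topdressing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheatnrec)
```

## The problem

Winter wheat takes up most of its nitrogen after stem elongation, so the
jointing-stage topdressing is the single most consequential fertilization
decision of the season. Applying a uniform rate ignores two things: the
plot-to-plot variability in crop N status that canopy reflectance can see,
and the fact that the profit-maximizing rate is below the yield-maximizing
rate whenever fertilizer costs money. `wheatnrec` implements a two-step
decision chain:

1. **State estimation.** Aboveground dry biomass (AGB, t ha^-1^) is
   estimated from NIR/red reflectance via EVI2 and a hierarchical linear
   model (HLM), then assimilated into a daily crop growth model by particle
   swarm optimization (PSO), re-estimating seven plot-level parameters.
2. **Decision.** The assimilated model is run over a topdressing-N grid
   (0-360 kg ha^-1^ in 10 kg steps); the *target yield* is the yield at the
   rate maximizing net benefit `E = Y*P_Y - N*P_N` (grain price 2.4, N price
   2.75 CNY kg^-1^), and the recommendation is the lowest grid rate whose
   yield meets that target.

The two readings of the decision rule ("lowest N meeting the target" vs
"maximize net income") coincide on a monotone response curve; we define the
target by the economic optimum and recommend by first attainment, reporting
both intermediate quantities so the audit trail is explicit. All
tie-breaking favors the lower rate.

## AGB monitoring model

EVI2 is `2.5*(NIR - R)/(NIR + 2.4*R + 1)`. The HLM has a level-1 regression
`AGB = beta0 + beta1*EVI2` whose coefficients are linear in thermal time:
`beta_j = g_j0 + g_j1*GDD`. We fit the algebraically identical interaction
form `AGB ~ GDD * EVI2` in one least-squares pass (`hlm_fit()`), because the
stagewise intermediate fits are not themselves of interest; a stagewise
method is kept for comparison. Predictions are deliberately unclamped so the
published coefficient set `(1.22, 0.02, -13.35, 0.38)` is reproduced exactly
(`hlm_predict(0, 0)` is 1.22); a clamp flag exists for map production where
negative biomass is a nuisance.

The GDD covariate carries no published scaling, and the published
coefficients only produce sensible biomass when the covariate is of order
50-120. The synthetic generator therefore uses cumulative GDD (degC d)
divided by 15 (`hlm_gdd_scale()`), which puts the four sampling stages in
that window; the scale is data, stored with the spectra, not hidden inside
the model functions.

## The growth surrogate

A full DSSAT/CERES-Wheat is out of scope; `simulate_season()` is a compact
daily surrogate exposing exactly the seven quantities the assimilation
tunes (P1D, PHINT, RDGS, SLPF, plant density, irrigation total, fertilizer
N). Structure per day:

* thermal time above 0 degC; phenophase thresholds (120/600/1100/1700 degC d
  scaled by PHINT/100) with development slowed by short photoperiod in
  proportion to P1D;
* potential growth = RUE (3.0 g MJ^-1^) x intercepted PAR (Beer's law,
  k = 0.5, LAI proportional to biomass) x a trapezoidal temperature factor
  x SLPF;
* a single-bucket water balance with root-depth-limited extraction (roots
  grow with RDGS);
* a mineral-N pool (initialized from NO3+NH4 via bulk density 1.3 g cm^-3^
  x 0.30 m), fed by fertilization events and organic-matter mineralization,
  drained by uptake; crop N demand follows the critical dilution curve
  `Nc(%) = 5.35 * W^-0.442`;
* actual growth = potential x min(water factor, N factor); yield = harvest
  index (0.45, softened by mean grain-fill stress with a floor of 0.5 of
  its potential) x final AGB, dry basis. The 14% moisture normalization
  used when reporting field yields is *not* applied internally.

Every constant lives in `crop_constants()` so a future adapter can replace
the module wholesale behind `register_crop_model()`.

Two constants were calibrated once, jointly, and then frozen:
`n_uptake_frac = 0.07` and `mineralization_per_om = 0.005`. The first
requirement was that the economic optimum topdressing declines by roughly
100 kg ha^-1^ as basal N rises from 0 to 135 kg ha^-1^ — the characteristic
shape of field N response curves. The second was identifiability: a twin
experiment's 200 kg ha^-1^ season dressing must remain recoverable from
stage-wise AGB under 5% observation noise, which fails when the soil N
supply saturates the crop early. Related to this, the N stress factor is
`tanh(supply/demand)` rather than `min(1, supply/demand)`: the hard Liebig
kink makes the AGB trajectory exactly flat above the saturation point, which
destroys the gradient the assimilation needs precisely where the economics
operate. tanh keeps a soft shoulder there, yet still reaches 1.0 exactly in
double precision under unlimited supply, preserving the stress-free limit.

**Parameter semantics.** The "fertilization amount" parameter (Table-range
0-400 kg ha^-1^) is the *season total*, split equally between the basal and
jointing applications, mirroring the trial protocol of equal urea splits.
The assimilated "jointing fertilization" is therefore half the recovered
total. In the recommendation step the basal half is held at its assimilated
value and only the topdressing event is varied across the grid.
Out-of-range parameters clamp silently in assimilation mode (swarm
excursions must not crash a cost evaluation) and raise errors in direct
mode.

## Assimilation

The cost is the mean relative squared error over the m observed stages,
`J = mean(((AGBs - AGBr)/AGBr)^2)`. The swarm uses the printed formulation
verbatim: 25 particles, c1 = c2 = 2.0, 100 iterations, initial velocities
uniform within 10% of each parameter range, and **no inertia weight**
(w = 1). Because w = 1 swarms can diverge, velocities are re-clamped to the
initialization fraction every step; bound violations clamp the position and
zero the velocity in that dimension. One particle is always seeded at the
calibrated initial values so the nominal parameterization is evaluated.
Random factors xi and eta are drawn per dimension per update. Convergence:
100 iterations, or earlier when the best cost improves by less than 1e-6
over 10 consecutive iterations. Equal-cost ties keep the first-found
position.

The pipeline's default assimilation frees only the fertilization parameter.
With more parameters free, near-flat ridges appear (e.g. fertilization vs
SLPF trade-offs fit the same AGB trajectory), and equivalent fits can imply
very different recommendations; collapsing the plot's N status into one
parameter makes the downstream recommendation a monotone function of the
crop state. Freeing all seven remains available through the parameter spec.

## Synthetic data: what it emulates, what it does not

`generate_weather()` draws a Beijing-like season: sinusoidal temperature
with AR(1) anomalies (tmax >= tmin by construction), Markov rain occurrence
with gamma amounts rescaled so the full-year total lands uniformly inside
the site's 400-620 mm range, and sunshine consistent with astronomical
daylength (solar radiation via Angstrom-Prescott, a = 0.25, b = 0.50).

`generate_experiment()` reproduces the modeling-trial layout: 2 varieties x
4 N rates (0/90/180/270 kg ha^-1^, equal basal/jointing split) x 4
replicates = 32 plots, sampled at the surrogate's own phenophase dates
(jointing, flag leaf, flowering, grain filling) = 128 AGB samples.
Destructive AGB observations carry 5% multiplicative lognormal noise; plot
soils vary by 10% lognormal CV on mineral N and water capacity; varieties
differ in SLPF (1.0 vs 0.95). Reflectance is synthesized by *inverting* the
published HLM at the truth AGB and adding Gaussian reflectance noise
(0.005), so in noiseless mode the EVI2 -> HLM round trip returns truth to
machine precision. This exercises the estimation chain but is deliberately
not a radiative-transfer simulation: a green test here establishes that the
pipeline machinery is correct, not that EVI2 physics holds in real
canopies. UAV geometry, mosaicking artifacts and illumination effects are
out of scope. Plot dimensions and per-stage stem counts are not emulated;
the destructive-sampling conversion (`plot_agb_from_sampling()`) keeps its
unit normalization as an explicit argument because the raw formula's
constants are not dimensionally t ha^-1^.

The pipeline-level monotonicity property (larger jointing AGB never gets a
larger recommendation) is asserted on the noiseless fixture: it is a
structural property of the decision rule, and observation noise is
exercised separately by the parameter-recovery criterion.

## Numerical choices and degenerate inputs

* Metrics: nRMSE is reported in percent of the observation mean; adjusted
  R^2^ uses the standard `1 - [SSE/(n-p-1)]/[SST/(n-1)]` form (the source
  formula as printed drops a square) with the predictor count an explicit
  argument.
* `fitness_j` refuses non-positive observations (relative error undefined).
* `hlm_fit` raises a singular-fit error naming the collinear columns when
  all samples share one GDD value.
* The reference power-law fit works on logs; R^2^ is reported on the log
  (fitting) scale and the original scale, both labelled. Its constructor
  enforces a > 0, b < 0 — fitting data with a positive trend is an error,
  not a silent sign flip.
* Recommendation ties and the economic-optimum tie both resolve to the
  lower N rate. An unattainable target yield returns an `infeasible` flag
  plus the maximum-yield rate rather than an error.
* Dates are ISO-8601 throughout; rasters are plain numeric CSV matrices,
  row-major, origin top-left, with NA masks propagated.

## Known limitations

* The surrogate is not DSSAT: absolute yields and optima are plausible for
  a North China Plain winter-wheat system but are not claimed to match any
  published simulator output.
* Single-season, single-nutrient, no pest/disease or lodging stress, no
  intra-season re-recommendation after jointing.
* AGB-based assimilation cannot discriminate N supply above the response
  shoulder; the tanh softening mitigates but does not remove this, and
  recovered rates in heavily over-fertilized scenarios are lower bounds on
  precision, not estimates of it.
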