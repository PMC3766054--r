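---
title: "Redox-balance scenario modelling of anaerobic yeast fermentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Redox-balance scenario modelling of anaerobic yeast fermentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redoxferm)
```

## The model

Anaerobic growth of *Saccharomyces cerevisiae* produces more NADH in
biosynthesis than it can reoxidise; glycerol formation is the canonical
sink. `redoxferm` compares two scenarios of a lumped central-carbon network
on a basis of 100 mmol combined hexose uptake (glucose and galactose pooled
at 180 g mol⁻¹; their catabolic routes are redox-neutral and ATP-yielding at
this lumping level, with Leloir-pathway ATP differences absorbable into the
ATP coefficients):

* **reference** — excess biosynthetic NADH is reoxidised by glycerol
  formation (1 NADH and 1 ATP per glycerol);
* **PRK/Rubisco** — phosphoribulokinase and Rubisco fix CO₂ onto
  ribulose-5-phosphate; the two 3-phosphoglycerate formed per carboxylation
  are fermented to ethanol. Net per mmol Ru5P: +2 ethanol, −2 NADH, 1 CO₂
  fixed against 2 emitted, and +1 ATP by default (two pyruvate-kinase ATP
  minus one PRK ATP).

Biosynthesis is lumped per Cmol biomass: it releases `n_nadh` NADH,
consumes `n_nadph` NADPH, and releases `n_co2_biomass` CO₂; biomass carbon
plus that CO₂ is drawn from hexose. Four balances close simultaneously —
carbon, NADH, NADPH, ATP — with the biomass flux tied to catabolic ATP
formation through a single `y_atp` (Cmol per mol ATP) **held identical in
both scenarios**, so any yield difference between scenarios is a pure
redox-accounting consequence, not a growth-efficiency assumption.

Ribulose-5-phosphate is preferentially drawn from the oxidative
pentose-phosphate pathway, whose flux is capped at half the biosynthetic
NADPH demand; remaining Ru5P comes from glycolytic intermediates through the
non-oxidative rearrangements (5/6 hexose per Ru5P). In the reference
scenario the oxidative branch still runs to meet the NADPH demand and the
Ru5P returns to glycolysis: the non-oxidative flux is then *signed
negative*, representing the transhydrogenase-type conversion
NADH + NADP⁺ → NAD⁺ + NADPH. We allow the same signed return flux in
capacity-limited engineered scenarios — without it the NADPH balance could
not close while Rubisco is CO₂-limited, and continuity at zero capacity
(engineered ≡ reference) would be lost.

Every min()-branch of this allocation rule leaves a purely linear system,
so each branch is solved exactly with dense `solve()` and feasibility
(non-negative fluxes, capacity respected) selects the branch. No iteration,
no tolerance tuning; balance residuals are recomputed from the returned
fluxes, independently of the solution path, and are required to be below
10⁻⁹ of the basis.

## Parameters

| parameter | units | default | rationale |
|---|---|---|---|
| `biomass_carbon_content` | g dry weight / Cmol | 24.6 | standard yeast biomass formula mass |
| `gamma_biomass` | e⁻ / Cmol | 4.2 | typical yeast degree of reduction |
| `n_nadh` | mol / Cmol | 0.230 | anaerobic biosynthetic NADH release; recalibrated from data in normal use |
| `n_nadph` | mol / Cmol | 0.150 | biosynthetic NADPH demand; *not identifiable* from reference yields (see below) |
| `n_co2_biomass` | mol / Cmol | derived | electron-balance closure of the biomass reaction unless given explicitly |
| `y_atp` | Cmol / mol ATP | 0.430 | ≈ 10.6 g biomass per mol ATP, anaerobic sugar-limited range |
| `atp_coeffs` | mol ATP / mmol flux | +2, −1, +1, −1, −7/6 | fermentation, glycerol, Rubisco route, oxPPP hexose activation, non-oxPPP Ru5P; the last two are this package's stated convention (1 activation ATP per hexose entering the oxidative branch; 7/6 ATP per Ru5P from an F6P/GAP mix), configurable because no canonical value exists at this lumping level |
| `k_evap` | h⁻¹ | 0.008 | first-order ethanol stripping in the bioreactor set-up |
| `K_co2` | mM | 0.26 | CO₂ half-saturation of the bacterial form-II Rubisco |
| `maintenance_atp` | mol ATP h⁻¹ g⁻¹ | 0 | fixed low dilution rate; no maintenance statement is made for these cultures. Enabling it requires a dilution rate to convert to a per-Cmol ATP drain |
| `henry_co2` | mM atm⁻¹ | 29.9 | CO₂ solubility in water at 30 °C; only used to translate a sparging-gas composition into dissolved CO₂, never hard-coded into balances |

Dissolved CO₂ enters the model in exactly one place: the Michaelis–Menten
factor `c/(K + c)` caps the attainable Rubisco flux. It never rescales the
balances; a CO₂-limited scenario is simply a capacity-capped one. With a
10% CO₂ sparge, Henry's law gives ≈3 mM ≫ `K_co2`, so such cultures are
effectively saturated — which is why the CO₂-sparged engineered condition
approaches complete glycerol elimination while the N₂-sparged one does not.

## Calibration and reconciliation

`calibrate_stoich()` inverts the reference-scenario balances so the solver
reproduces a measured yield set exactly: `n_nadh` from the NADH balance,
`y_atp` from the ATP balance, the biosynthetic CO₂ release from carbon
closure, and the implied biomass degree of reduction from electron closure.
Two points deserve emphasis:

* **`n_nadph` is structurally unidentifiable** from reference yields: the
  oxidative-PPP transhydrogenase cycle is carbon- and electron-neutral, so
  any prior value reproduces the same yields. It is kept at its prior and
  the unit tests verify this invariance.
* **Measured yield sets rarely close their books.** Printed chemostat
  yields at face value recover ≈96% of carbon in a closed model with
  conventional biomass coefficients. Exact reproduction in a model whose
  residuals must vanish therefore requires putting the gap somewhere; we
  put it in the biosynthetic CO₂ release (carbon closure) and let the
  biomass degree of reduction follow from electron closure. The calibrated
  `n_co2_biomass` and `gamma_biomass` are thus *reconciled effective*
  coefficients, not elemental-analysis values. Targets whose apparent
  carbon recovery falls outside 0.95–1.05 are rejected outright.

The zero-growth limit (`y_atp = 0`, biomass yield 0) is admitted as a valid
parameter point: it realises pure alcoholic fermentation (200 mmol ethanol
and CO₂ per 100 mmol hexose) and is the natural boundary case for the
calibration.

Engineered-strain steady states are encoded the same way (see
`chemostat_fixture()`): the biosynthetic cofactor coefficients are inherited
from the same-sparge reference calibration, the Rubisco flux follows from
the NADH balance of the engineered yields, and that flux doubles as the
condition's capacity.

## What the model predicts

Calibrated to a typical glycerol-producing reference chemostat
(0.083 g g⁻¹, 1.56 mol mol⁻¹ ethanol, 0.14 mol mol⁻¹ glycerol), the
unlimited engineered scenario redirects ~14 mmol NADH-equivalents from
glycerol into ~7.9 mmol Ru5P carboxylations, predicting ≈1.70 mol mol⁻¹
ethanol (+9%) and zero glycerol. The theoretical ceiling of this family of
scenarios is parameterisation-dependent — with other defensible biomass
stoichiometries the gain ranges up to the mid-teens percent — which is why
the package's tests treat the gain as a range property (0.08–0.15 for
data-calibrated parameters) rather than a point target, and separately
verify *optimality*: the engineered-scenario ethanol flux equals a
brute-force linear-programming maximum (vertex enumeration over the same
balances) to 10⁻⁶ relative on 100 random parameter sets.

## The synthetic-data generator

The generator exists so that every pipeline stage is testable end-to-end
without external data. It emulates the study design: duplicate independent
cultures; sugar-limited chemostats at D = 0.05 h⁻¹ on 12.5 + 12.5 g l⁻¹
glucose/galactose under N₂ or 10% CO₂ sparging; batch cultures on
20 g l⁻¹ galactose with a lag phase; first-order ethanol evaporation; and
small multiplicative Gaussian measurement noise (relative SD 0.01,
truncated at zero — concentrations are positive and HPLC/dry-weight errors
are approximately relative).

Chemostat records are synthesised by *inverting the analysis*: broth
ethanol is the production-equivalent concentration times `D/(D + k_evap)`,
off-gas CO₂ follows from the net evolution rate through the molar volume
(24.9 l mol⁻¹ at 30 °C) and gas flow (30 l h⁻¹ per l broth, chosen to give
sub-percent off-gas increments as in typical lab set-ups). Noiseless
round-trips through the analysis are therefore exact to numerical precision
— that is a *consistency* check of generator and analysis, not evidence
about real cultures.

Batch series use the simplest growth-coupled model: constant biomass during
the lag, exponential growth at `mu_max` with fixed yields until sugar
exhaustion, exact within-step exponential updates on a 0.02 h grid sampled
hourly, ethanol decaying first-order throughout. There is no Monod term, no
product inhibition, no CO₂ mass-transfer dynamics and no expression burden:
only µmax, lag and final yields are meaningful, which is all the batch
analysis consumes. Batch absolute yields are an assumption: the CO₂-sparged
chemostat yields adjusted by the reported batch strain effects (glycerol
×0.40, ethanol ×1.08, biomass unchanged), with µmax = 0.13 h⁻¹ for both
strains and lag times of 2 h vs 12 h.

Determinism: a fixed seed gives bitwise-identical output; each replicate
draws from its own sub-stream (`seed + replicate`).

## Numerical and procedural choices

* **Evaporation correction.** The chemostat correction uses the
  steady-state balance `(D + k) C / D` — at steady state, production per
  volume is `(D + k) C`. It is exactly the inverse of the generator's
  attenuation, is the identity at `k = 0`, and can be switched off for
  sensitivity checks. The batch correction reconstructs cumulative
  production as `C(t) + k ∫C dτ` with a trapezoidal integral on the sample
  grid; on hourly samples the residual error is ~10⁻⁴ relative.
* **Growth-rate fitting.** µmax is the slope of `ln X` over the longest
  contiguous window whose log-linear fit reaches R² ≥ 0.999 (ties broken by
  higher R²); plateau windows are excluded, and an entirely flat series
  returns µ = 0 with undefined lag. The stringent default matters: at
  R² ≥ 0.99 the maximal window absorbs lag and stationary samples and
  biases µ several percent low on clean data. Lag is the back-extrapolation
  of the fitted line to the inoculum level.
* **Replicate spread** is reported as average ± mean deviation (the
  convention for duplicate cultures); significance testing still uses the
  sample variance (two-sided, equal-variance t-test, threshold 0.02).
  Headline percent changes are rounded to integer percent with full
  precision retained.
* **Degenerate inputs.** Infeasible scenarios raise an error naming the
  violated balance instead of clipping fluxes at zero; records are
  validated schema-first with row-numbered messages; zero reference yields
  flag percent changes as undefined rather than dividing by zero; enzyme
  activities below the detection limit are censored (`"< lod"`) with
  censoring monotone in the reading.
* **Projection arithmetic.** Redirecting a lost sugar fraction `f` into
  product made from the remaining `1 − f` adds `V·f/(1 − f)`; headline
  figures round to one significant digit.

## Problem sizes

The test-suite simulations are sized for interactive runs: 100 random
parameter sets for the optimality cross-check, 25–40 for balance-closure
sweeps, 1000 noisy replicates for the noise-propagation check, hourly batch
sampling over 48 h. All finish in a few seconds; the acceptance script
analyses two duplicate-culture conditions and runs in under a minute.

## Known limitations

* The model is stoichiometric only: no kinetics beyond the single CO₂
  saturation cap, no thermodynamics, no genome-scale context, no regulation
  (e.g. galactose-inducible PRK expression) and no expression burden.
* Calibration reconciles measurement gaps into two biomass coefficients;
  with strongly non-closing data those coefficients stop being
  biologically interpretable even though the fit is exact.
* The ATP costs of Ru5P sourcing are conventions, stated and configurable;
  conclusions that hinge on a percent-level gain difference should sweep
  them.
* The generator's noise model is independent across quantities and
  replicates; real cultures share systematic errors (calibration drift,
  feed-medium batches) that it does not emulate, so passing round-trip
  tests bounds software correctness, not experimental accuracy.
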