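# redoxferm

Stoichiometric redox-balance scenario modelling of anaerobic *Saccharomyces
cerevisiae* fermentation, with an analysis pipeline for chemostat and batch
fermentation data and a synthetic-data generator.

## The problem

In anaerobic, ethanol-producing yeast cultures, biosynthesis releases excess
NADH that cannot be reoxidised by respiration. The cell disposes of it by
reducing part of the sugar to glycerol, which typically claims several
percent of the feedstock in industrial bioethanol production. Functional
expression of two Calvin-cycle enzymes — phosphoribulokinase (PRK) and
ribulose-1,5-bisphosphate carboxylase (Rubisco) — offers an alternative
sink: CO₂, the main by-product of fermentation, is fixed onto
ribulose-5-phosphate and the resulting two 3-phosphoglycerate are fermented
to ethanol, reoxidising two NADH per Ru5P. Glycerol formation can then be
replaced by extra ethanol formation.

`redoxferm` implements this comparison as an exactly balanced lumped
reaction network. On a basis of 100 mmol combined hexose uptake (glucose and
galactose pooled, 180 g mol⁻¹), the pathway fluxes
*v*(fermentation), *v*(glycerol), *v*(oxPPP), *v*(non-oxPPP), *v*(Rubisco)
and the biomass flux *x* (Cmol) satisfy four linear balances:

- **carbon** — hexose consumed by all routes sums to the basis;
- **NADH** — `n_NADH · x = v_glycerol + 2 v_Rubisco`;
- **NADPH** — `2 v_oxPPP = n_NADPH · x` (the oxidative pentose-phosphate
  pathway runs exactly to the biosynthetic NADPH demand; surplus
  ribulose-5-phosphate is recycled through the non-oxidative reactions,
  a transhydrogenase-type NADH→NADPH conversion);
- **ATP** — `x = Y_ATP × (net catabolic ATP)`, with the biomass yield on
  ATP identical in both scenarios.

The system is piecewise linear and solved exactly per branch; the engineered
scenario minimises glycerol subject to an optional Rubisco capacity, capped
by Michaelis–Menten CO₂ saturation (`K_CO2 = 0.26 mM`, a low-affinity
bacterial form-II enzyme). `calibrate_stoich()` inverts the balances so the
reference scenario reproduces measured chemostat yields exactly; the
calibrated model then predicts the engineered strain.

The analysis side mirrors how such fermentations are evaluated: molar yields
on pooled hexose with a first-order ethanol-evaporation correction
(`k_evap = 0.008 h⁻¹`; steady-state factor `(D + k)/D` in chemostats,
trapezoidal reconstruction in batch), off-gas CO₂ balances, carbon/electron
recovery checks, log-linear µmax and lag fitting, equal-variance t-tests for
strain comparisons, and detection-limit censoring for enzyme assays.

## Worked example

```r
library(redoxferm)

fit <- redox_model(yield_set(Y_biomass = 0.083, Y_ethanol = 1.56,
                             Y_glycerol = 0.14))
summary(fit)
```

```
Redox-balance scenario model of anaerobic yeast fermentation

  yield                   reference  PRK/Rubisco
  biomass (g g-1)             0.083        0.090
  ethanol (mol mol-1)         1.560        1.701
  glycerol (mol mol-1)        0.140        0.000

  ethanol-yield gain: 9.0%
  glycerol reduction: 100%

Calibrated coefficients (per Cmol biomass):
       n_nadh       n_nadph n_co2_biomass         y_atp gamma_biomass
       0.2305        0.1500        0.4069        0.4254        5.4667

max |calibration residual| = 2.78e-17
max |balance residual| = 4.55e-13 per 100 mmol hexose
```

Read: calibrated to a glycerol-producing reference chemostat
(0.083 g g⁻¹ biomass, 1.56 mol mol⁻¹ ethanol, 0.14 mol mol⁻¹ glycerol),
the model predicts that full replacement of glycerol formation by the
PRK/Rubisco route raises the ethanol yield by ~9% to 1.70 mol mol⁻¹ —
within 2% of the 1.73 mol mol⁻¹ measured for the engineered strain —
while all four balances stay closed to numerical precision.

Projections and synthetic data:

```r
project_global_gain(110, 0.04)$additional_rounded
#> [1] 5     # extra billion litres if a 4% glycerol loss is redirected

rec <- generate_chemostat(chemostat_fixture("prk_rubisco_co2"), noise_sd = 0)
summary(chemostat_yields(rec))
#> Yields (average +/- mean deviation, n = 2 replicates - evaporation-corrected )
#>   Y_biomass  0.095 +/- 0 g g-1
#>   Y_ethanol  1.73 +/- 0 mol mol-1
#>   Y_glycerol 0.01 +/- 0 mol mol-1
```

A thin command-line wrapper is installed under `inst/cli/redoxferm`
(subcommands `solve`, `calibrate`, `gain`, `project`, `simulate`, `analyze`,
`compare`).

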