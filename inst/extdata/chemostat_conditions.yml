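# The four anaerobic chemostat conditions of the study design: two strains
# (glycerol-producing reference; PRK/Rubisco-expressing) under two sparging
# gases (pure N2; 10% CO2 / 90% N2), sugar-limited at D = 0.05 h^-1 on
# 12.5 g/l glucose + 12.5 g/l galactose. Each condition is encoded by its
# steady-state yields (biomass g/g; ethanol and glycerol mol/mol hexose,
# evaporation-corrected) and the inlet-gas CO2 fraction. Engineered
# conditions name the same-sparge reference condition used to anchor the
# biosynthetic NADH/NADPH coefficients during calibration.
shared:
  dilution_rate: 0.05      # h^-1
  glucose_in: 12.5         # g/l
  galactose_in: 12.5       # g/l
  residual_glucose: 0.1    # g/l, sugar-limited steady state
  residual_galactose: 0.1  # g/l
  gas_flow: 30.0           # l gas h^-1 per l broth
  noise_sd: 0.01           # relative sd of multiplicative measurement noise
  replicates: 2            # independent duplicate cultures
  seed: 1
conditions:
  reference_n2:
    mode: reference
    sparge: n2
    co2_in: 0.0
    Y_biomass: 0.083
    Y_ethanol: 1.56
    Y_glycerol: 0.14
  reference_co2:
    mode: reference
    sparge: co2
    co2_in: 0.10
    Y_biomass: 0.084
    Y_ethanol: 1.56
    Y_glycerol: 0.12
  prk_rubisco_n2:
    mode: prk_rubisco
    sparge: n2
    co2_in: 0.0
    Y_biomass: 0.093
    Y_ethanol: 1.73
    Y_glycerol: 0.04
    reference_condition: reference_n2
  prk_rubisco_co2:
    mode: prk_rubisco
    sparge: co2
    co2_in: 0.10
    Y_biomass: 0.095
    Y_ethanol: 1.73
    Y_glycerol: 0.01
    reference_condition: reference_co2
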