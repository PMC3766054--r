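# Synthetic anaerobic batch conditions on 20 g/l galactose (10% CO2 sparge).
# Absolute batch yields are an assumption documented in the methods vignette:
# the CO2-sparged chemostat yields adjusted by the reported batch effects
# (glycerol reduced by 60%, ethanol increased by 8%, biomass unchanged);
# growth rates equal for both strains with a 10 h lag-phase difference.
shared:
  sugar_0: 20.0        # g/l galactose
  inoculum: 0.15       # g/l biomass
  t_end: 48            # h
  sample_interval: 1.0 # h
  step: 0.02           # h, internal integration step
  noise_sd: 0.01
  replicates: 2
  seed: 1
conditions:
  reference:
    mu_max: 0.13           # h^-1
    lag: 2.0               # h
    Y_biomass_mass: 0.084  # g/g
    Y_ethanol: 1.56        # mol/mol
    Y_glycerol: 0.12       # mol/mol
  prk_rubisco:
    mu_max: 0.13
    lag: 12.0
    Y_biomass_mass: 0.084
    Y_ethanol: 1.6848      # 1.56 * 1.08
    Y_glycerol: 0.048      # 0.12 * 0.40
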