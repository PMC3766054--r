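# Default stoichiometric parameters of the anaerobic scenario model.
# Units: biomass_carbon_content g/Cmol; gamma_biomass e-/Cmol; n_* mol per
# Cmol biomass; y_atp Cmol biomass per mol ATP; k_evap h^-1; K_co2 mM;
# maintenance_atp mol ATP h^-1 g^-1; henry_co2 mM CO2 per atm (water, 30 C).
# n_co2_biomass is omitted here: it is derived from the electron balance of
# the biomass reaction.
biomass_carbon_content: 24.6
gamma_biomass: 4.2
n_nadh: 0.230
n_nadph: 0.150
y_atp: 0.430
k_evap: 0.008
K_co2: 0.26
maintenance_atp: 0.0
henry_co2: 29.9
atp_coeffs:
  ferment: 2.0          # net ATP per hexose fermented to 2 ethanol + 2 CO2
  glycerol: -1.0        # per glycerol (activation ATP of the hexose half)
  rubisco: 1.0          # per Ru5P: 2 pyruvate-kinase ATP minus 1 PRK ATP
  oxppp_hexose: -1.0    # hexose activation on entry to the oxidative PPP
  nonoxppp_ru5p: -1.1666666666666667  # 7/6 per Ru5P from an F6P/GAP mix
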