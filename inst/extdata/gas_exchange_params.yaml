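# Three-compartment gas-exchange parameters (alveolar air / lung tissue / capillary blood).
# Transcribed from the source parameter table with two label corrections applied on ingest:
#  - the tissue conversion coefficient is printed under a duplicated "sigma_A" label and is
#    read here as sigma_T;
#  - the second diffusion rate is printed under a duplicated "D_TA" label and is read here
#    as D_TB, with its printed range (6.7-10)e-12 kept and the mid-range value 8.0e-12 used
#    whenever a point value is needed.
gas_exchange:
  V_A: 1.9e-7        # alveolar air-space volume, L
  V_T: 4.2e-8        # lung-tissue volume, L
  V_B: 7.5e-9        # capillary-blood volume, L
  sigma_A: 2.5e-5    # partial pressure -> molar concentration, alveolar air, M/mm
  sigma_T: 1.2e-6    # partial pressure -> molar concentration, lung tissue, M/mm
  sigma_B: 1.2e-6    # partial pressure -> molar concentration, capillary blood, M/mm
  D_TA: 2.4e-12      # diffusion rate, tissue <-> alveolar air, L/s
  D_TB: 8.0e-12      # diffusion rate, tissue <-> capillary blood, L/s (mid-range)
  D_TB_range: [6.7e-12, 1.0e-11]
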