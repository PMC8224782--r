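# Default cabozantinib profile for the whole-body PBPK model.
# Units: see field comments. fu_plasma is stored as a FRACTION: cabozantinib
# is ~99.7% bound to human plasma proteins, i.e. 0.24% unbound -> 0.0024.
drug:
  molecular_weight: 501.50          # g/mol
  pKa_base: 6.32                    # conjugate-acid pKa (monoprotic base)
  fu_plasma: 0.0024                 # fraction unbound in plasma (0.24 %)
  logP: 4.40                        # lipophilicity used by the model
  solubility_ref: 7.72e-3           # mg/mL
  solubility_ref_pH: 6.5
  km_cyp3a4: 0.97                   # umol/L
  kcat_cyp3a4: 0.67                 # 1/min
  km_mrp2: 10.0                     # umol/L
  kcat_mrp2: 2111.11                # 1/min
  mrp2_ref_conc: 0.09               # umol protein / L liver tissue
  transcellular_permeability: 1.70e-4   # cm/min
  partition_method: rodgers_rowland
  permeability_method: perfusion_limited
  kp_rbc: 0.0                       # drug confined to plasma within blood
formulations:
  tablet:
    weibull_t50: 36.00              # min, fasted state
    weibull_shape: 1.29
  capsule:
    weibull_t50: 45.00              # min, fasted state
    weibull_shape: 5.00
    lag_min: 15.0                   # hard-gelatin shell rupture lag
  solution:
    solution_solubility_scale: 0.8  # mild suspension-like solubility reduction
regimen:
  dose: 140                         # mg
  formulation: tablet
  route: oral
  interval: 24                      # h
  n_doses: 1
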