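name: rifampin
physchem:
  molecular_weight: 822.940000000000055
  logP: 2.7
  compound_type: neutral
  pKa: .na.real
  fu_plasma: 0.17
  solubility_water: 1.4
clearance:
  hepatic_plasma_cl: 1.3
  hepatic_cl_multiple_dose: 1.3
  gfr_fraction: 1.0
transporters: []
interactions:
- target: ABCB1
  mechanism: induction
  emax: 2.5
  ec50: 0.34
  applies_to: victim
- target: ABCB1
  mechanism: competitive_inhibition
  ki: 9.1
  applies_to: victim
- target: ABCG2
  mechanism: competitive_inhibition
  ki: 14.0
  applies_to: victim
- target: ABCG2
  mechanism: static_fold
  fold: 1.5
  applies_to: victim
- target: OATP1B1
  mechanism: induction
  emax: 0.383
  ec50: 0.34
  applies_to: self_clearance
  clearance_fraction: 0.45
- target: AADAC
  mechanism: induction
  emax: 0.985
  ec50: 0.34
  applies_to: self_clearance
  clearance_fraction: 0.55
intestinal_permeability: 1.0e-05
organ_permeability: .na.real
kp_scale: 1.0
partition_overrides:
  gut: 0.7
  liver: 0.7
  kidney: 0.7
  rest: 0.7

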