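name: linezolid
physchem:
  molecular_weight: 337.350000000000023
  logP: 0.55
  compound_type: monoprotic_base
  pKa: 1.7
  fu_plasma: 0.69
  solubility_water: 3.0
clearance:
  hepatic_plasma_cl: 0.65
  hepatic_cl_multiple_dose: 0.5
  gfr_fraction: 0.15
transporters:
- transporter_id: ABCB1
  kcat: 72.0
  km: 51.0
  reference_concentration: 0.077
  clint_assay: 2.1
  abundance_assay: 10.300000000000001
- transporter_id: ABCG2
  kcat: 720.0
  km: 53.0
  reference_concentration: 0.025
  clint_assay: 16.0
  abundance_assay: 13.18
interactions: []
intestinal_permeability: 9.0e-06
organ_permeability: 0.0009
kp_scale: 0.62
partition_overrides: ~

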