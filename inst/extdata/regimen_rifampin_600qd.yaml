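route: oral
dose_mg: 600.0
n_doses: 14
interval_h: 24.0
start_time_h: 0.0
infusion_duration_min: 30.0

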