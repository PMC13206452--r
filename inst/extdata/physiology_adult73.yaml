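body_weight: 73.0
volumes:
  lumen: 1.0
  gut: 1.2
  portal: 0.25
  liver: 1.8
  kidney: 0.31
  art: 0.9
  ven: 2.1
  rest: 60.0
flows:
  gut: 0.9
  hepatic_artery: 0.35
  kidney: 0.66
  rest: 1.35
cardiac_output_plasma: 3.26
gfr: 0.12
absorption_s2v: 2800.0
gut_transit_time: 180.0
blood_plasma_ratio: 1.0
relative_expression:
  gut:
    ABCB1: 0.15
    ABCG2: 0.008
  kidney:
    ABCB1: 0.95
    ABCG2: 0.046
  liver:
    ABCB1: 0.0
    ABCG2: 0.0

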