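# Example optimization configuration: HILIC x RP-LC with sub-2-um columns.
# Units: flows uL/min (f2 optionally mL/min under f2_ml_min), times min,
# volumes uL, lengths mm, particle size um, pressure bar.
instrument:
  dwell_d1: 13
  dwell_d2: 55
  ec_var_d1: 0
  ec_var_d2: 3.8
  temp_d1: 30
  temp_d2: 60
  strong_d1: water
  strong_d2: acn
  V_inj_d1: 5
  reeq_time: 0.1
  n_max: 400
columns:
  d1: {length: 150, id: 1.0, dp: 1.7, porosity: 0.6, flow_resistance: 700,
       max_pressure: 1000}
  d2: {length: 50, id: 3.0, dp: 1.8, porosity: 0.55, flow_resistance: 700,
       max_pressure: 1200}
ranges:
  f1: [17, 26]
  f2_ml_min: [2]
  ts: [0.55, 0.75]
  fmu: [68]
  loop: [80]
  makeup_composition: 0
  d1_gradients:
    - {phi_init: 0.01, phi_final: 0.25, t_grad: 55}
  d2_gradients:
    - {phi_init: 0.01, phi_final: 0.55}   # t_grad omitted: fills the cycle
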