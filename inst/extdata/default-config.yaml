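posttranscription:
  alpha_M: 0.0
  alpha_A: 58.52000000000000313
  alpha_S: 2.61363636363636376
  'N': 22.0
  delta_M: 0.20000000000000001
  delta_A: 0.0014
  delta_S: 0.25
  k_M: 1.0
  k_S: 1.0
  p_M: 1.0
  p_S: 1.0
  n_sos: 20.0
  cell_volume: 0.65000000000000002
sos:
  alpha_Mlex: 12.0
  alpha_Mrec: 5.0
  alpha_Ms: 5.0
  alpha_Ml: 1.0
  beta_lex: 5.0
  beta_rec: 2.0
  delta_Mlex: 0.29999999999999999
  delta_Mrec: 0.29999999999999999
  delta_Ms: 0.20000000000000001
  delta_Le: 0.005
  delta_R: 0.5
  beta_L: 1.0
  delta_L: 0.05
  k_on: 0.05
  k_off: 0.20000000000000001
  c_p: 0.0
schedule:
- - 0.0
  - 0.0
- - 200.0
  - 6.0
- - 500.0
  - 0.0
run:
  seed: 1
  n_realizations: 500
  t_max: 700.0
  grid_dt: 1.0
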