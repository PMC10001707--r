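geometry:
  volume: 200000.0
  area: 100000.0
  depth: 2.0
eco:
  mypc: 2.8
  deac: 0.1
  tetg: 1.14
  kn: 0.05
  kp: 0.009
  kmdm: 0.04
  chl_to_c: 25.0
  n_to_c: 0.18
  p_to_c: 0.024
  i_k: 80.0
  v_settle_iss: 0.05
  v_settle_dc: 0.1
  nh4_pref: 0.01
  tet_miner: 1.0
optics:
  gamma: 8.9
  a_w: 0.05
  a_phi: 0.02
  a_iss: 0.08
  a_dc: 0.24
  b_w: 0.0019
  b_phi: 0.12
  b_iss: 0.025
  b_dc: 0.0125
  mu0: 0.856
endmembers:
  sw:
    nh4: 1.65
    no3: 0.35
    ip: 0.2
    ss_total: 60.0
    iss: 45.0
  rw:
    nh4: 5.0
    no3: 10.0
    ip: 0.5
    ss_total: 10.0
    iss: 10.0
  om_to_c: 0.5
  iss_fraction: 0.75
loads:
  runoff_area: 67000.0
  runoff_coefficient: 0.9
  runoff_conc:
    nh4: 2.5
    no3: 4.0
    ip: 0.64
forcing:
  t_mean: 16.0
  t_amp: 12.0
  t_peak_doy: 207.5
  t_noise_sd: 0.8
  latitude: 34.299999999999997
  solar_constant: 1100.0
  atm_transmission: 0.7
  cloud_mean: 0.72
  cloud_sd: 0.15
  rain_monthly:
  - 7.0
  - 10.0
  - 22.0
  - 40.0
  - 54.0
  - 60.0
  - 99.0
  - 75.0
  - 92.0
  - 60.0
  - 24.0
  - 6.0
  rain_events:
  - 3.0
  - 4.0
  - 6.0
  - 8.0
  - 9.0
  - 9.0
  - 10.0
  - 9.0
  - 10.0
  - 8.0
  - 5.0
  - 3.0
scenario:
  p_grid_step: 0.05
  q_min: 0.05
  q_max: 0.77
  q_step: 0.03
  resolution: 0.005
  sd_target_cm: 70.0
  drift_tol: 0.01
  chunk_days: 28.0
  max_days: 365.0
integration:
  dt: 1800.0
  output_dt: 5400.0
seed: 1.0
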