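transitions:
  W:
    W: 0.899
    S: 0.097
    A: 0.004
  S:
    W: 0.817
    S: 0.176
    A: 0.007
  A:
    W: 0.271
    S: 0.052
    A: 0.677
transition_sd:
  W:
    S: 0.029
    A: 0.002
  S:
    W: 0.038
    A: 0.003
  A:
    W: 0.044
    S: 0.046
utilities:
  W: 0.99
  S: 0.7
  A: 0.31
utility_sd:
  W: 0.016
  S: 0.072
  A: 0.07
effect:
  rr: 0.76
  ci_low: 0.63
  ci_high: 0.92
  table_sd: 0.274
  use_table_sd: no
  level: 0.95
costs:
- name: feno_per_patient_day
  mean: 2.2
  sd: 1.08
  family: gamma
  sa_low: 1.2
  sa_high: 4.2
- name: ward_daily
  mean: 95.049999999999997
  sd: 8.529999999999999
  family: gamma
  sa_low: 80.230000000000004
  sa_high: 102.010000000000005
- name: ward_los_days
  mean: 5.5
  sd: 1.04
  family: gamma
  sa_low: 4.0
  sa_high: 8.0
- name: picu_daily
  mean: 406.519999999999982
  sd: 18.890000000000001
  family: gamma
  sa_low: 350.430000000000007
  sa_high: 430.259999999999991
- name: picu_los_days
  mean: 10.9
  sd: 3.26
  family: gamma
  sa_low: 7.75
  sa_high: 15.050000000000001
- name: ed_daily
  mean: 64.299999999999997
  sd: 19.27
  family: gamma
  sa_low: 51.189999999999998
  sa_high: 71.459999999999994
- name: specialist
  mean: 10.67
  sd: 1.72
  family: gamma
  sa_low: 10.31
  sa_high: 11.01
- name: chest_physiotherapy
  mean: 5.15
  sd: 1.23
  family: gamma
  sa_low: 4.9
  sa_high: 5.39
- name: chest_radiography
  mean: 2.84
  sd: 0.73
  family: gamma
  sa_low: 2.7
  sa_high: 2.98
- name: other_imaging
  mean: 0.01
  sd: 0.08
  family: gamma
  sa_low: 0.0
  sa_high: 0.02
- name: cbc
  mean: 1.12
  sd: 0.28
  family: gamma
  sa_low: 1.05
  sa_high: 1.17
- name: other_laboratory
  mean: 4.4
  sd: 0.37
  family: gamma
  sa_low: 4.23
  sa_high: 4.47
- name: oxygen
  mean: 1.37
  sd: 0.41
  family: gamma
  sa_low: 1.28
  sa_high: 1.45
- name: nebulization
  mean: 16.23
  sd: 4.52
  family: gamma
- name: lev
  mean: 1.1
  sd: 0.16
  family: gamma
  sa_low: 1.07
  sa_high: 1.13
- name: antibiotics
  mean: 1.21
  sd: 0.49
  family: gamma
  sa_low: 1.11
  sa_high: 1.3
- name: corticosteroids
  mean: 0.08
  sd: 4.18
  family: gamma
  sa_low: 0.0
  sa_high: 0.9
- name: bronchodilators
  mean: 0.04
  sd: 0.02
  family: gamma
  sa_low: 0.03
  sa_high: 0.04
- name: other_drugs
  mean: 0.65
  sd: 0.04
  family: gamma
  sa_low: 0.6
  sa_high: 0.68
- name: medical_devices
  mean: 10.24
  sd: 2.66
  family: gamma
  sa_low: 9.710000000000001
  sa_high: 10.76
- name: indirect_per_day
  mean: 17.239999999999998
  sd: 4.3
  family: gamma
  sa_low: 16.379999999999999
  sa_high: 18.07
strategies:
- name: standard
  rr_exacerbation: 1.0
  addon_cost_per_cycle: 0.0
  uses_effect_rr: no
- name: feno
  rr_exacerbation: 0.76
  addon_cost_per_cycle: 15.400000000000002
  uses_effect_rr: yes
  addon_component: feno_per_patient_day
settings:
  n_cycles: 52
  cycle_length_years: 0.019230769230769
  wtp: 20000.0
  psa_iterations: 1000
  seed: 1
  population_for_pevpi: ~
  half_cycle_correction: no
  rr_targets:
  - W->A
  - S->A
recipe:
  p_picu: 0.0
  calibration:
    W: 1.0
    S: 1.0
    A: 1.0
  overrides: {}
init:
  W: 1.0
  S: 0.0
  A: 0.0
dirichlet_reference:
  W: S
  S: W
  A: W
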