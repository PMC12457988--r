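seed: 1
synth:
  n_individuals: 420
  n_years: 17
  use_fitted_model: yes
model:
  m_mean: 0.07
  target_lambda: 1.015
  s_neo: 0.6
  fecundity_sd: 0.106
  birth_sex_ratio: 0.5
  generation_time: 7.2
scenarios:
  m_values:
  - 0.0
  - 0.07
  - 0.23
  horizon_years: 30
  n_reps: 1000
  initial_n: 100
threshold:
  enabled: no
  n_reps: 200
  m_range:
  - 0.05
  - 0.15
  tolerance: 0.02
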