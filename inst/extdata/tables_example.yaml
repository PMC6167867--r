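# Example configuration for run_tables(): the power grid at theta_A =
# theta_B = 0.5, m1_A = 2, varying m1_B and the per-group sample size.
# Every scenario inherits the defaults and may override any
# scenario_config() argument.
defaults:
  theta_A: 0.5
  theta_B: 0.5
  lambda0_A: 1
  lambda0_B: 1
  m1_A: 2
  c_p: 0
  n_reps: 1000
  M: 10
scenarios:
  - {m1_B: 1.5,  n_per_group: 50}
  - {m1_B: 1.25, n_per_group: 50}
  - {m1_B: 1.0,  n_per_group: 50}
  - {m1_B: 1.5,  n_per_group: 100}
  - {m1_B: 1.25, n_per_group: 100}
  - {m1_B: 1.0,  n_per_group: 100}
  - {m1_B: 1.5,  n_per_group: 200}
  - {m1_B: 1.25, n_per_group: 200}
  - {m1_B: 1.0,  n_per_group: 200}
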