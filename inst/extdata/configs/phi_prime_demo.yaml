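task: phi_prime_demo
scale: paper
seeds: [1]
task_params:
  sigma_xi: 0.05
  tau_xi: 10
  T_pres_ticks: 100
  n_pres: 20
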