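task: cartpole
scale: paper
seeds: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10]
epochs: 5
network:
  g_err: 6.0e-4
  eta: 50.0
task_params:
  variant: realistic
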