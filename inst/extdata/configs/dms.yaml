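task: dms
scale: paper
seeds: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10]
epochs: 10
network:
  g_l: 0.3
  eta: 1.0
task_params:
  eval_every: 1
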