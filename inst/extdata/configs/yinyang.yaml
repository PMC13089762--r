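task: yinyang
scale: paper
seeds: [1, 2, 3]
epochs: 50
network:
  eta: 5.0
  sigma_L: 0.1
  b_noise: 0.1
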