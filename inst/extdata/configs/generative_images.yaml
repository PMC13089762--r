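task: generative_images
scale: paper
seeds: [1, 2, 3]
epochs: 800
network:
  eta: 3.0
  sigma_L: 0.03
task_params:
  side: 8
  hidden: [32, 32]
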