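task: teacher_student
scale: paper
seeds: [1, 2, 3, 4, 5]
epochs: 1000
network:
  eta: 2.0
task_params:
  complexity: 3
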