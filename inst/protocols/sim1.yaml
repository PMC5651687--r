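name: sim1
seed: 1
structure:
  n_classes: 3
  n_members: 3
  roles:
  - A
  - B
  - C
  trained_relations:
  - AB
  - BC
  n_comparisons: 3
parameters:
  beta: 0.2
  theta: 0.7
  activation_gate: 0.85
  decay_multiplier: 0.25
  test_beta_fraction: 0.25
  weight_min: -1.0
  weight_max: 1.0
  pair_eligibility: both_active
  propagation: single_wave
  max_stage_repeats: 100
tracked_pairs:
- - A1
  - B1
- - B1
  - C1
- - A1
  - C1
stages:
- name: AB-BC training
  phase: train
  trial_counts:
    A1B1: 1
    B1C1: 1
  shuffle: no
  n_blocks: 30
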