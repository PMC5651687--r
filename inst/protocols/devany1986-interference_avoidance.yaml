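name: devany1986-interference_avoidance
seed: 1
structure:
  n_classes: 2
  n_members: 3
  roles:
  - A
  - B
  - C
  trained_relations:
  - AB
  - AC
  n_comparisons: 2
parameters:
  beta: 0.1
  theta: 0.72
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
- - A1
  - C1
- - B1
  - C1
- - B2
  - C2
stages:
- name: A1B1 alone
  phase: train
  trial_counts:
    A1B1: 45
  shuffle: no
  n_blocks: 1
- name: A2B2 alone
  phase: train
  trial_counts:
    A2B2: 45
  shuffle: no
  n_blocks: 1
- name: AB and AC mixed
  phase: train
  trial_counts:
    AB: 15
    AC: 15
  shuffle: yes
  n_blocks: 1
- name: transitivity test
  phase: test
  trial_counts:
    B1C1: 1
    C1B1: 1
    B2C2: 1
    C2B2: 1
  shuffle: yes
  n_blocks: 1
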