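name: devany1986-typical
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
- - A1
  - C1
- - B1
  - C1
- - B2
  - C2
stages:
- name: A1B1
  phase: train
  trial_counts:
    A1B1: 10
  shuffle: no
  n_blocks: 1
  criterion: 9/10
  consecutive: no
- name: A2B2
  phase: train
  trial_counts:
    A2B2: 10
  shuffle: no
  n_blocks: 1
  criterion: 9/10
  consecutive: no
- name: A1B1, A2B2
  phase: train
  trial_counts:
    A1B1: 5
    A2B2: 5
  shuffle: yes
  n_blocks: 1
  criterion: 9/10
  consecutive: no
- name: A1C1
  phase: train
  trial_counts:
    A1C1: 10
  shuffle: no
  n_blocks: 1
  criterion: 9/10
  consecutive: no
- name: A2C2
  phase: train
  trial_counts:
    A2C2: 10
  shuffle: no
  n_blocks: 1
  criterion: 9/10
  consecutive: no
- name: A1C1, A2C2
  phase: train
  trial_counts:
    A1C1: 5
    A2C2: 5
  shuffle: yes
  n_blocks: 1
  criterion: 9/10
  consecutive: no
- name: all relations mixed
  phase: train
  trial_counts:
    A1B1: 2
    A2B2: 2
    A1C1: 2
    A2C2: 2
  shuffle: yes
  n_blocks: 1
  criterion: 7/8
  consecutive: no
- name: maintenance without reinforcement
  phase: test
  trial_counts:
    A1B1: 2
    A2B2: 2
    A1C1: 2
    A2C2: 2
  shuffle: yes
  n_blocks: 1
  criterion: 8/8
  consecutive: no
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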