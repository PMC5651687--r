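name: spencer1996-equal_trials
seed: 1
structure:
  n_classes: 3
  n_members: 7
  roles:
  - A
  - B
  - C
  - D
  - E
  - F
  - G
  trained_relations:
  - AB
  - BC
  - CD
  - DE
  - EF
  - FG
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
- - A1
  - C1
- - A1
  - D1
- - A1
  - G1
stages:
- name: equal trials per relation
  phase: train
  trial_counts:
    A1B1: 1
    B1C1: 1
    C1D1: 1
    D1E1: 1
    E1F1: 1
    F1G1: 1
    A2B2: 1
    B2C2: 1
    C2D2: 1
    D2E2: 1
    E2F2: 1
    F2G2: 1
    A3B3: 1
    B3C3: 1
    C3D3: 1
    D3E3: 1
    E3F3: 1
    F3G3: 1
  shuffle: yes
  n_blocks: 65
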