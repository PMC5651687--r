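name: sidman1982
seed: 1
structure:
  n_classes: 3
  n_members: 4
  roles:
  - A
  - B
  - C
  - D
  trained_relations:
  - AB
  - AC
  - DC
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
  - D1
- - B1
  - C1
- - A1
  - D1
stages:
- name: 'AB: A1B1, A2B2'
  phase: train
  trial_counts:
    A1B1: 10
    A2B2: 10
  shuffle: yes
  n_blocks: 1
  criterion: 19/20
  consecutive: no
- name: 'AB: A1B1, A3B3'
  phase: train
  trial_counts:
    A1B1: 10
    A3B3: 10
  shuffle: yes
  n_blocks: 1
  criterion: 19/20
  consecutive: no
- name: 'AB: A2B2, A3B3'
  phase: train
  trial_counts:
    A2B2: 10
    A3B3: 10
  shuffle: yes
  n_blocks: 1
  criterion: 19/20
  consecutive: no
- name: 'AB: all classes'
  phase: train
  trial_counts:
    A1B1: 10
    A2B2: 10
    A3B3: 10
  shuffle: yes
  n_blocks: 1
  criterion: 29/30
  consecutive: no
- name: 'AC: A1C1, A2C2'
  phase: train
  trial_counts:
    A1C1: 10
    A2C2: 10
  shuffle: yes
  n_blocks: 1
  criterion: 19/20
  consecutive: no
- name: 'AC: A1C1, A3C3'
  phase: train
  trial_counts:
    A1C1: 10
    A3C3: 10
  shuffle: yes
  n_blocks: 1
  criterion: 19/20
  consecutive: no
- name: 'AC: A2C2, A3C3'
  phase: train
  trial_counts:
    A2C2: 10
    A3C3: 10
  shuffle: yes
  n_blocks: 1
  criterion: 19/20
  consecutive: no
- name: 'AC: all classes'
  phase: train
  trial_counts:
    A1C1: 10
    A2C2: 10
    A3C3: 10
  shuffle: yes
  n_blocks: 1
  criterion: 29/30
  consecutive: no
- name: AB and AC mixed
  phase: train
  trial_counts:
    A1B1: 5
    A2B2: 5
    A3B3: 5
    A1C1: 5
    A2C2: 5
    A3C3: 5
  shuffle: yes
  n_blocks: 1
  criterion: 29/30
  consecutive: no
- name: 'DC: D1C1, D2C2'
  phase: train
  trial_counts:
    D1C1: 10
    D2C2: 10
  shuffle: yes
  n_blocks: 1
  criterion: 19/20
  consecutive: no
- name: 'DC: D1C1, D3C3'
  phase: train
  trial_counts:
    D1C1: 10
    D3C3: 10
  shuffle: yes
  n_blocks: 1
  criterion: 19/20
  consecutive: no
- name: 'DC: D2C2, D3C3'
  phase: train
  trial_counts:
    D2C2: 10
    D3C3: 10
  shuffle: yes
  n_blocks: 1
  criterion: 19/20
  consecutive: no
- name: 'DC: all classes'
  phase: train
  trial_counts:
    D1C1: 10
    D2C2: 10
    D3C3: 10
  shuffle: yes
  n_blocks: 1
  criterion: 29/30
  consecutive: no
- name: AB, AC and DC mixed
  phase: train
  trial_counts:
    A1B1: 5
    A2B2: 5
    A3B3: 5
    A1C1: 5
    A2C2: 5
    A3C3: 5
    D1C1: 5
    D2C2: 5
    D3C3: 5
  shuffle: yes
  n_blocks: 1
  criterion: 44/45
  consecutive: no
- name: equivalence test
  phase: test
  trial_counts:
    A1B1: 1
    A2B2: 1
    A3B3: 1
    A1C1: 1
    A2C2: 1
    A3C3: 1
    D1C1: 1
    D2C2: 1
    D3C3: 1
    D1B1: 1
    D2B2: 1
    D3B3: 1
    B1D1: 1
    B2D2: 1
    B3D3: 1
    A1D1: 1
    A2D2: 1
    A3D3: 1
    B1C1: 1
    B2C2: 1
    B3C3: 1
    C1B1: 1
    C2B2: 1
    C3B3: 1
    C1D1: 1
    C2D2: 1
    C3D3: 1
  shuffle: yes
  n_blocks: 1
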