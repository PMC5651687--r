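name: spencer1996
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
- name: 1. AB
  phase: train
  trial_counts:
    AB: 48
  shuffle: yes
  n_blocks: 1
  criterion: 44/48
  consecutive: no
- name: 2. BC
  phase: train
  trial_counts:
    AB: 24
    BC: 24
  shuffle: yes
  n_blocks: 1
  criterion: 44/48
  consecutive: no
- name: 3. CD
  phase: train
  trial_counts:
    AB: 12
    BC: 12
    CD: 24
  shuffle: yes
  n_blocks: 1
  criterion: 44/48
  consecutive: no
- name: 4. DE
  phase: train
  trial_counts:
    AB: 8
    BC: 8
    CD: 8
    DE: 24
  shuffle: yes
  n_blocks: 1
  criterion: 44/48
  consecutive: no
- name: 5. EF
  phase: train
  trial_counts:
    AB: 6
    BC: 6
    CD: 6
    DE: 6
    EF: 24
  shuffle: yes
  n_blocks: 1
  criterion: 44/48
  consecutive: no
- name: 6. FG
  phase: train
  trial_counts:
    AB: 3
    BC: 3
    CD: 3
    DE: 6
    EF: 9
    FG: 24
  shuffle: yes
  n_blocks: 1
  criterion: 44/48
  consecutive: no
- name: 7. baseline maintenance (no reinforcement)
  phase: test
  trial_counts:
    AB: 3
    BC: 3
    CD: 3
    DE: 3
    EF: 3
    FG: 3
  shuffle: yes
  n_blocks: 1
  criterion: 17/18
  consecutive: no
- name: equivalence test
  phase: test
  trial_counts:
    AB: 3
    BC: 3
    CD: 3
    DE: 3
    EF: 3
    FG: 3
    BA: 3
    CB: 3
    DC: 3
    ED: 3
    FE: 3
    GF: 3
    AC: 3
    AD: 3
    AE: 3
    AF: 3
    AG: 3
    BD: 3
    BE: 3
    BF: 3
    BG: 3
    CE: 3
    CF: 3
    CG: 3
    DF: 3
    DG: 3
    EG: 3
    CA: 3
    DA: 3
    EA: 3
    FA: 3
    GA: 3
    DB: 3
    EB: 3
    FB: 3
    GB: 3
    EC: 3
    FC: 3
    GC: 3
    FD: 3
    GD: 3
    GE: 3
  shuffle: yes
  n_blocks: 1
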