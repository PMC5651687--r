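# eqsim

Hebbian network simulation of stimulus equivalence classes.

## What this is for

Stimulus equivalence is the behavioral phenomenon in which perceptually
unrelated stimuli become interchangeable after only a subset of their
pairwise relations is trained: teach AB and BC in matching-to-sample format
and a learner also matches BA, CB (symmetry) and AC (transitivity) without
reinforcement. `eqsim` is for researchers in behavior analysis and
computational cognitive neuroscience who want to simulate how such classes
form, how *relatedness* (graded associative strength) develops for trained
and derived relations, how it falls off with nodal distance, and how
training schedules change all of the above — including a learning-disability
parameter regime in which trained relations survive but derived
transitivity collapses.

## The model

One localist unit per stimulus in a single fully interconnected layer.
Connection weights W start at 0, are symmetric, bounded in [−1, 1], and are
read as the relatedness of the two stimuli. On a trial the sample unit is
clamped to 1, comparison units compete on their raw weight from the sample
(ties broken at random; losers held at 0 by lateral inhibition), and the
rest of the layer receives one wave of spreading activation through a gated
logistic:

    X_j = 1 / (1 + exp(-net_j))   if net_j > 0.85,  else 0

Every pair of coactive units is then updated from the pre-trial weights with
a supervised, threshold-split Hebbian rule (learning rate β = 0.2,
coactivation threshold θ = 0.7 by default):

    X_i X_j >= θ :  ΔW = s · β_eff · (X_i X_j − W)     s = ±1 feedback
    X_i X_j <  θ :  ΔW = 0.25 · β_eff · (−W)           feedback-blind decay

with β_eff = β in training and β/4 in unreinforced test phases. Transitive
relations emerge because a well-trained connection (W > 0.85) lets the
sample evoke an absent stimulus, whose coactivation with the clamped units
then clears θ and trains the never-presented pair.

## Worked example

Train one three-member class by alternating A1B1 and B1C1 trials for 30
epochs and watch the derived A1C1 relation switch on:

```r
library(eqsim)
run <- run_protocol(make_protocol("sim1"), seed = 1)
round(tail(run$trajectory, 3), 3)
#>        A1B1  B1C1  A1C1
#> [28,] 0.920 0.936 0.857
#> [29,] 0.921 0.936 0.857
#> [30,] 0.921 0.936 0.857
emergence_epoch(run, "A1C1")
#> [1] 10
```

The two trained weights approach their asymptotes while the
never-reinforced A1C1 weight — exactly zero for the first nine epochs —
emerges at epoch 10, once W(A1,B1) = 1 − 0.8⁹ ≈ 0.87 exceeds the 0.85
activation gate, and stays below both trained weights thereafter.

Multi-seed replication of a packaged study, aggregated by nodal distance:

```r
replicate_study("devany1986", "learning_disability", seeds = 1:5)
#> <eq_replication> devany1986/learning_disability over 5 seeds
#>  distance category mean_weight  sd_weight n_pairs
#>         0 baseline   0.8320023 0.00365164       4
#>         1   1-node   0.0197500 0.02065504       2
```

Under the raised LTP threshold (θ = 0.72, β = 0.1) the trained baseline
relations still reach ~0.83 but the derived transitive relations stay near
0 — the model's account of failed transitivity in learners with severe
learning disabilities, and the package's `interference_avoidance` variant
shows the schedule that rescues it.

Other entry points: `eq_network()` / `run_trial()` for single-trial
mechanics, `stage_spec()` / `protocol_spec()` / `run_protocol()` for custom
curricula, `generate_structure()` for linear-series vs one-to-many
topologies, `relatedness_by_category()` / `nodal_profile()` /
`accuracy_summary()` for reporting, YAML protocol round-tripping via
`write_protocol_yaml()`, and a command-line wrapper
(`inst/cli/eqsim.R`: `replicate`, `run`, `protocols list`, `report`).

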