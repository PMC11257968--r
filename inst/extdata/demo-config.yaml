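# Demo configuration for the full pipeline (clock all --config ...).
# n = 20,000 persons: completes on one CPU well inside 15 minutes.
seed: 20
out_dir: mortclock_demo
generator:
  n_persons: 20000
splits:
  train_year: 2018
  valid_year: 2019
  test_year: 2020
model:
  rnn:
    max_epochs: 8
    patience: 5
  comparators: []
evaluation:
  bootstrap: 1000
  bins: 10
fairness:
  permutations: 1000
# a 2% person sample keeps the Shapley stage a few minutes on one CPU;
# raise toward the 6.5% default when runtime is not a concern
explain:
  mode: sampled
  fraction: 0.02
  n_permutations: 20
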