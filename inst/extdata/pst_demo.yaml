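# Two-stimulus probabilistic selection demonstration:
# one pair with 90% / 20% reward contingencies, 10 trials.
task:
  type: pst
  contingencies:
  - [0.9, 0.2]
  n_trials: 10
execution:
  seeds: [1]
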