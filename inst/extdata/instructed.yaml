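# Instructed probabilistic selection: 90% / 20% pair, PFC/HC instruction
# biasing the worse (20%) stimulus, 30 trials.
task:
  type: instructed
  p_first: 0.9
  p_second: 0.2
  instructed: 2
  n_trials: 30
execution:
  seeds: [1]
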