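# Probabilistic reversal learning: 90% / 20% pair, contingencies swapped
# every 20 trials (first swap effective at trial 21), 100 trials.
task:
  type: reversal
  p_first: 0.9
  p_second: 0.2
  block: 20
  n_trials: 100
execution:
  seeds: [1]
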