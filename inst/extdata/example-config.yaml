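# Example run configuration for the whisknovelty command line.
plant:
  natural_freq_hz: 20
  damping: 1.0
  k: 0.05
drive:
  mode: periodic
  freq_hz: 3
contacts:
  threshold: 0.999
filter:
  mode: sensorimotor
  learning_rate: 5.0e-4
experiment:
  duration_s: 400
  n_trials: 10
  base_seed: 1
output:
  dir: whisknovelty-output
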