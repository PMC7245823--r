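# Run configuration for the `fit` entry point (see ?cli_fit).
input: panel.csv
columns:
  id: id
  wave: wave
  outcome: y
  fixed: [f1]
  time_dependent: [x1, x2]
max_lag: 3
alpha: 0.05
adjust: none
drop_incomplete: false
out_dir: out
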