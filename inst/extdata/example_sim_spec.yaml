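# Generator spec for the `simulate` entry point (see ?cli_simulate).
N: 500
T: 4
J: 2
beta0: 0.25
beta_fixed: 0.3
beta_lag:
  - [0.8, 0.4, 0.2, 0.3]
  - [-0.5, 0.3, -0.2, 0.0]
rho: 0.0
feedback: 0.0
seed: 1
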