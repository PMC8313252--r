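name: broadbalk
substrate:
  InsP6: 0.95
  InsP5 [1/3-OH]: 0.05
days:
- 0.0
- 1.0
- 2.0
- 3.0
- 4.0
- 5.0
- 6.0
- 7.0
- 8.0
noise:
  baseline: 0.0
  sd: 0.002
seed: 20201221
community:
  enzymes: []
  sorption: 3.0
  pi_uptake: 5.0
  t_lag: 0.0
  tau: 0.25
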