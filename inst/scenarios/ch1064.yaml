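name: ch1064
substrate:
  InsP6: 0.95
  InsP5 [1/3-OH]: 0.05
days:
- 0.0
- 1.0
- 2.0
noise:
  baseline: 0.0
  sd: 0.002
seed: 20201221
community:
  enzymes:
  - name: buttiauxella_appa
    class_label: HAP_6PHYTASE
    w:
    - 0.2
    - 0.001
    - 0.001
    - 0.001
    - 0.05
    - 10.0
    k: 0.12
    mix: 1.0
  sorption: 0.0
  pi_uptake: 0.0
  t_lag: 0.0
  tau: 0.25
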