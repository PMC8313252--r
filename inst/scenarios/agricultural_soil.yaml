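name: agricultural_soil
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
  enzymes:
  - name: bsubtilis_bpp
    class_label: BPP_3PHYTASE
    w:
    - 0.01
    - 0.01
    - 1.0
    - 0.01
    - 0.01
    - 0.01
    k: 0.12
    mix: 3.0
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
    mix: 0.3
  - name: ac12_minpp
    class_label: MINPP
    w:
    - 0.02
    - 0.05
    - 0.02
    - 0.8
    - 0.5
    - 1.6
    k: 0.2
    mix: 2.0
  sorption: 0.0
  pi_uptake: 0.0
  t_lag: 3.0
  tau: 0.25
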