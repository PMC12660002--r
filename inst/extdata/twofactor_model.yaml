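# Synthetic demo data: two-factor independent-cluster model, 6 MVs.
m: 6
d: 2
pattern:
  - [1, 0]
  - [1, 0]
  - [1, 0]
  - [0, 1]
  - [0, 1]
  - [0, 1]
identification: unit_factor_variance
mean_structure: true
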