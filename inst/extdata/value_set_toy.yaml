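# Round-number toy value set used in examples and tests.
name: toy
intercept_deduction: 0.05
level2_deductions:
  MO: 0.04
  SC: 0.04
  UA: 0.04
  PD: 0.04
  AD: 0.04
level3_deductions:
  MO: 0.30
  SC: 0.30
  UA: 0.30
  PD: 0.30
  AD: 0.30
n3_deduction: 0.20
floor: -0.75
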