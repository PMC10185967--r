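# Synthetic Korean-style EQ-5D-3L value set (additive N3 model).
# NOT the published Korean tariff: coefficients are synthetic stand-ins of
# realistic magnitude, constrained so the worst state (3,3,3,3,3) scores
# exactly -0.17, matching the documented Korean index range [-0.17, 1.00].
# Edit or replace with licensed coefficients for substantive use.
name: korean_3l_synthetic
intercept_deduction: 0.050
level2_deductions:
  MO: 0.096
  SC: 0.046
  UA: 0.051
  PD: 0.037
  AD: 0.043
level3_deductions:
  MO: 0.418
  SC: 0.136
  UA: 0.208
  PD: 0.151
  AD: 0.158
n3_deduction: 0.049
floor: -0.170
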