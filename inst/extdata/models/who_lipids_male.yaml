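# SYNTHETIC coefficient set — see who_lipids_female.yaml header for rationale.
model: who_lipids
stratum: {sex: male}
form: cox
units: {total_cholesterol: mmol/L, sbp: mmHg}
age_range: [40, 74]
s0: 0.93
center: 7.125
terms:
  - coef: 0.080
    factors: [{var: age, transform: identity}]
  - coef: 0.013
    factors: [{var: sbp, transform: identity}]
  - coef: 0.14
    factors: [{var: total_cholesterol, transform: identity}]
  - coef: 0.65
    factors: [{var: diabetes, transform: identity}]
  - coef: 0.65
    factors: [{var: smoker, transform: identity}]
source: "SYNTHETIC stand-in for the WHO laboratory-based CVD risk model, men; constructed for this package (see who_lipids_female.yaml header)."
retrieved: "2026-09-29"
checksum: "n:5;sum:1.533000"
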