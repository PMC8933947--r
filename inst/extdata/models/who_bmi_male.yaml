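# SYNTHETIC coefficient set — see who_lipids_female.yaml header for rationale.
model: who_bmi
stratum: {sex: male}
form: cox
units: {sbp: mmHg, bmi: kg/m2}
age_range: [40, 74]
s0: 0.93
center: 7.725
terms:
  - coef: 0.080
    factors: [{var: age, transform: identity}]
  - coef: 0.013
    factors: [{var: sbp, transform: identity}]
  - coef: 0.050
    factors: [{var: bmi, transform: identity}]
  - coef: 0.65
    factors: [{var: smoker, transform: identity}]
source: "SYNTHETIC stand-in for the WHO non-laboratory (BMI) CVD risk model, men; constructed for this package (see who_lipids_female.yaml header)."
retrieved: "2026-09-29"
checksum: "n:4;sum:0.793000"
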