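# SYNTHETIC coefficient set — see who_lipids_female.yaml header for rationale.
# Non-laboratory version: BMI replaces cholesterol and the diabetes indicator
# is omitted (the non-laboratory charts require no blood test).
model: who_bmi
stratum: {sex: female}
form: cox
units: {sbp: mmHg, bmi: kg/m2}
age_range: [40, 74]
s0: 0.95
center: 7.42
terms:
  - coef: 0.075
    factors: [{var: age, transform: identity}]
  - coef: 0.014
    factors: [{var: sbp, transform: identity}]
  - coef: 0.045
    factors: [{var: bmi, transform: identity}]
  - coef: 0.60
    factors: [{var: smoker, transform: identity}]
source: "SYNTHETIC stand-in for the WHO non-laboratory (BMI) CVD risk model, women; constructed for this package (see who_lipids_female.yaml header)."
retrieved: "2026-09-29"
checksum: "n:4;sum:0.734000"
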