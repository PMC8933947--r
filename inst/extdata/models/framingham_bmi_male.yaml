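model: framingham_bmi
stratum: {sex: male}
form: cox
units: {sbp: mmHg, bmi: kg/m2}
age_range: [30, 74]
s0: 0.88431
center: 23.9388
terms:
  - coef: 3.11296
    factors: [{var: age, transform: log}]
  - coef: 0.79277
    factors: [{var: bmi, transform: log}]
  - coef: 1.85508
    factors: [{var: sbp_untreated, transform: log}]
  - coef: 1.92672
    factors: [{var: sbp_treated, transform: log}]
  - coef: 0.70953
    factors: [{var: smoker, transform: identity}]
  - coef: 0.53160
    factors: [{var: diabetes, transform: identity}]
source: "Framingham general cardiovascular risk profile, office-based (BMI) equation, men; Cox model coefficient table of the original general-CVD publication."
retrieved: "2026-09-29"
checksum: "n:6;sum:8.928660"
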