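model: framingham_bmi
stratum: {sex: female}
form: cox
units: {sbp: mmHg, bmi: kg/m2}
age_range: [30, 74]
s0: 0.94833
center: 26.0145
terms:
  - coef: 2.72107
    factors: [{var: age, transform: log}]
  - coef: 0.51125
    factors: [{var: bmi, transform: log}]
  - coef: 2.81291
    factors: [{var: sbp_untreated, transform: log}]
  - coef: 2.88267
    factors: [{var: sbp_treated, transform: log}]
  - coef: 0.61868
    factors: [{var: smoker, transform: identity}]
  - coef: 0.77763
    factors: [{var: diabetes, transform: identity}]
source: "Framingham general cardiovascular risk profile, office-based (BMI) equation, women; Cox model coefficient table of the original general-CVD publication."
retrieved: "2026-09-29"
checksum: "n:6;sum:10.324210"
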