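model: pce
stratum: {sex: male, ancestry: black}
form: cox
units: {total_cholesterol: mg/dL, hdl: mg/dL, sbp: mmHg}
age_range: [40, 79]
s0: 0.8954
center: 19.54
terms:
  - coef: 2.469
    factors: [{var: age, transform: log}]
  - coef: 0.302
    factors: [{var: total_cholesterol, transform: log}]
  - coef: -0.307
    factors: [{var: hdl, transform: log}]
  - coef: 1.916
    factors: [{var: sbp_treated, transform: log}]
  - coef: 1.809
    factors: [{var: sbp_untreated, transform: log}]
  - coef: 0.549
    factors: [{var: smoker, transform: identity}]
  - coef: 0.645
    factors: [{var: diabetes, transform: identity}]
source: "Pooled Cohort Equations, 10-year ASCVD risk; African-American men stratum; ACC/AHA 2013 risk-assessment guideline coefficient table."
retrieved: "2026-09-29"
checksum: "n:7;sum:7.383000"
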