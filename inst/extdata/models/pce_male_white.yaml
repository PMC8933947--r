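model: pce
stratum: {sex: male, ancestry: white}
form: cox
units: {total_cholesterol: mg/dL, hdl: mg/dL, sbp: mmHg}
age_range: [40, 79]
s0: 0.9144
center: 61.18
terms:
  - coef: 12.344
    factors: [{var: age, transform: log}]
  - coef: 11.853
    factors: [{var: total_cholesterol, transform: log}]
  - coef: -2.664
    factors: [{var: age, transform: log}, {var: total_cholesterol, transform: log}]
  - coef: -7.990
    factors: [{var: hdl, transform: log}]
  - coef: 1.769
    factors: [{var: age, transform: log}, {var: hdl, transform: log}]
  - coef: 1.797
    factors: [{var: sbp_treated, transform: log}]
  - coef: 1.764
    factors: [{var: sbp_untreated, transform: log}]
  - coef: 7.837
    factors: [{var: smoker, transform: identity}]
  - coef: -1.795
    factors: [{var: age, transform: log}, {var: smoker, transform: identity}]
  - coef: 0.658
    factors: [{var: diabetes, transform: identity}]
source: "Pooled Cohort Equations, 10-year ASCVD risk; white/other men stratum; ACC/AHA 2013 risk-assessment guideline coefficient table."
retrieved: "2026-09-29"
checksum: "n:10;sum:25.573000"
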