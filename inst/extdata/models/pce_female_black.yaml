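model: pce
stratum: {sex: female, ancestry: black}
form: cox
units: {total_cholesterol: mg/dL, hdl: mg/dL, sbp: mmHg}
age_range: [40, 79]
s0: 0.9533
center: 86.61
terms:
  - coef: 17.114
    factors: [{var: age, transform: log}]
  - coef: 0.940
    factors: [{var: total_cholesterol, transform: log}]
  - coef: -18.920
    factors: [{var: hdl, transform: log}]
  - coef: 4.475
    factors: [{var: age, transform: log}, {var: hdl, transform: log}]
  - coef: 29.291
    factors: [{var: sbp_treated, transform: log}]
  - coef: -6.432
    factors: [{var: age, transform: log}, {var: sbp_treated, transform: log}]
  - coef: 27.820
    factors: [{var: sbp_untreated, transform: log}]
  - coef: -6.087
    factors: [{var: age, transform: log}, {var: sbp_untreated, transform: log}]
  - coef: 0.691
    factors: [{var: smoker, transform: identity}]
  - coef: 0.874
    factors: [{var: diabetes, transform: identity}]
source: "Pooled Cohort Equations, 10-year ASCVD risk; African-American women stratum; ACC/AHA 2013 risk-assessment guideline coefficient table."
retrieved: "2026-09-29"
checksum: "n:10;sum:49.766000"
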