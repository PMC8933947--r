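model: pce
stratum: {sex: female, ancestry: white}
form: cox
units: {total_cholesterol: mg/dL, hdl: mg/dL, sbp: mmHg}
age_range: [40, 79]
s0: 0.9665
center: -29.18
terms:
  - coef: -29.799
    factors: [{var: age, transform: log}]
  - coef: 4.884
    factors: [{var: age, transform: logsq}]
  - coef: 13.540
    factors: [{var: total_cholesterol, transform: log}]
  - coef: -3.114
    factors: [{var: age, transform: log}, {var: total_cholesterol, transform: log}]
  - coef: -13.578
    factors: [{var: hdl, transform: log}]
  - coef: 3.149
    factors: [{var: age, transform: log}, {var: hdl, transform: log}]
  - coef: 2.019
    factors: [{var: sbp_treated, transform: log}]
  - coef: 1.957
    factors: [{var: sbp_untreated, transform: log}]
  - coef: 7.574
    factors: [{var: smoker, transform: identity}]
  - coef: -1.665
    factors: [{var: age, transform: log}, {var: smoker, transform: identity}]
  - coef: 0.661
    factors: [{var: diabetes, transform: identity}]
source: "Pooled Cohort Equations, 10-year ASCVD risk; white/other women stratum; ACC/AHA 2013 risk-assessment guideline coefficient table."
retrieved: "2026-09-29"
checksum: "n:11;sum:-14.372000"
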