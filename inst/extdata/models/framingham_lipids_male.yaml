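model: framingham_lipids
stratum: {sex: male}
form: cox
units: {total_cholesterol: mg/dL, hdl: mg/dL, sbp: mmHg}
age_range: [30, 74]
s0: 0.88936
center: 23.9802
terms:
  - coef: 3.06117
    factors: [{var: age, transform: log}]
  - coef: 1.12370
    factors: [{var: total_cholesterol, transform: log}]
  - coef: -0.93263
    factors: [{var: hdl, transform: log}]
  - coef: 1.93303
    factors: [{var: sbp_untreated, transform: log}]
  - coef: 1.99881
    factors: [{var: sbp_treated, transform: log}]
  - coef: 0.65451
    factors: [{var: smoker, transform: identity}]
  - coef: 0.57367
    factors: [{var: diabetes, transform: identity}]
source: "Framingham general cardiovascular risk profile, lipid-based equation, men; Cox model coefficient table of the original general-CVD publication."
retrieved: "2026-09-29"
checksum: "n:7;sum:8.412260"
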