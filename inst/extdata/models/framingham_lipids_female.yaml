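model: framingham_lipids
stratum: {sex: female}
form: cox
units: {total_cholesterol: mg/dL, hdl: mg/dL, sbp: mmHg}
age_range: [30, 74]
s0: 0.95012
center: 26.1931
terms:
  - coef: 2.32888
    factors: [{var: age, transform: log}]
  - coef: 1.20904
    factors: [{var: total_cholesterol, transform: log}]
  - coef: -0.70833
    factors: [{var: hdl, transform: log}]
  - coef: 2.76157
    factors: [{var: sbp_untreated, transform: log}]
  - coef: 2.82263
    factors: [{var: sbp_treated, transform: log}]
  - coef: 0.52873
    factors: [{var: smoker, transform: identity}]
  - coef: 0.69154
    factors: [{var: diabetes, transform: identity}]
source: "Framingham general cardiovascular risk profile, lipid-based equation, women; Cox model coefficient table of the original general-CVD publication."
retrieved: "2026-09-29"
checksum: "n:7;sum:9.634060"
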