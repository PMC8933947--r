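# SYNTHETIC coefficient set. The WHO 2019 laboratory-based risk-chart model is
# published with region-recalibrated coefficients that were not available for
# transcription; this file encodes a constructed stand-in in the same functional
# form (sex-stratified Cox, mmol/L lipid units) with hazard-ratio magnitudes and
# a baseline survival anchored to chart-like 10-year risks. Suitable for
# pipeline exercise and method comparison machinery, not for clinical use.
model: who_lipids
stratum: {sex: female}
form: cox
units: {total_cholesterol: mmol/L, sbp: mmHg}
age_range: [40, 74]
s0: 0.95
center: 6.85
terms:
  - coef: 0.075
    factors: [{var: age, transform: identity}]
  - coef: 0.014
    factors: [{var: sbp, transform: identity}]
  - coef: 0.12
    factors: [{var: total_cholesterol, transform: identity}]
  - coef: 0.70
    factors: [{var: diabetes, transform: identity}]
  - coef: 0.60
    factors: [{var: smoker, transform: identity}]
source: "SYNTHETIC stand-in for the WHO laboratory-based CVD risk model, women; constructed for this package (see file header)."
retrieved: "2026-09-29"
checksum: "n:5;sum:1.509000"
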