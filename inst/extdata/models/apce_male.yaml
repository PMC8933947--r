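model: apce
stratum: {sex: male}
form: logistic
units: {total_cholesterol: mg/dL, hdl: mg/dL, sbp: mmHg}
age_range: [40, 79]
terms:
  - coef: -11.679980
    factors: [{var: one, transform: identity}]
  - coef: 0.064200
    factors: [{var: age, transform: identity}]
  - coef: 0.482835
    factors: [{var: black, transform: identity}]
  - coef: -0.000061
    factors: [{var: sbp, transform: squared}]
  - coef: 0.038950
    factors: [{var: sbp, transform: identity}]
  - coef: 2.055533
    factors: [{var: bp_treated, transform: identity}]
  - coef: 0.842209
    factors: [{var: diabetes, transform: identity}]
  - coef: 0.895589
    factors: [{var: smoker, transform: identity}]
  - coef: 0.193307
    factors: [{var: tc_hdl_ratio, transform: identity}]
  - coef: -0.014207
    factors: [{var: sbp, transform: identity}, {var: bp_treated, transform: identity}]
  - coef: 0.011609
    factors: [{var: sbp, transform: identity}, {var: black, transform: identity}]
  - coef: -0.119460
    factors: [{var: black, transform: identity}, {var: bp_treated, transform: identity}]
  - coef: 0.000025
    factors: [{var: age, transform: identity}, {var: sbp, transform: identity}]
  - coef: -0.077214
    factors: [{var: black, transform: identity}, {var: diabetes, transform: identity}]
  - coef: -0.226771
    factors: [{var: black, transform: identity}, {var: smoker, transform: identity}]
  - coef: -0.117749
    factors: [{var: black, transform: identity}, {var: tc_hdl_ratio, transform: identity}]
  - coef: 0.004190
    factors: [{var: black, transform: identity}, {var: bp_treated, transform: identity}, {var: sbp, transform: identity}]
  - coef: -0.000199
    factors: [{var: black, transform: identity}, {var: age, transform: identity}, {var: sbp, transform: identity}]
source: "Revised Pooled Cohort Equations refit on updated cohorts (logistic form, men); elastic-net logistic coefficient table of the revising publication. Recalibration constants not applied."
retrieved: "2026-09-29"
checksum: "n:18;sum:-7.647194"
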