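model: apce
stratum: {sex: female}
form: logistic
units: {total_cholesterol: mg/dL, hdl: mg/dL, sbp: mmHg}
age_range: [40, 79]
terms:
  - coef: -12.823110
    factors: [{var: one, transform: identity}]
  - coef: 0.106501
    factors: [{var: age, transform: identity}]
  - coef: 0.432440
    factors: [{var: black, transform: identity}]
  - coef: 0.000056
    factors: [{var: sbp, transform: squared}]
  - coef: 0.017666
    factors: [{var: sbp, transform: identity}]
  - coef: 0.731678
    factors: [{var: bp_treated, transform: identity}]
  - coef: 0.943970
    factors: [{var: diabetes, transform: identity}]
  - coef: 1.009790
    factors: [{var: smoker, transform: identity}]
  - coef: 0.151318
    factors: [{var: tc_hdl_ratio, transform: identity}]
  - coef: -0.008580
    factors: [{var: age, transform: identity}, {var: black, transform: identity}]
  - coef: -0.003647
    factors: [{var: sbp, transform: identity}, {var: bp_treated, transform: identity}]
  - coef: 0.006208
    factors: [{var: sbp, transform: identity}, {var: black, transform: identity}]
  - coef: 0.152968
    factors: [{var: black, transform: identity}, {var: bp_treated, transform: identity}]
  - coef: -0.000153
    factors: [{var: age, transform: identity}, {var: sbp, transform: identity}]
  - coef: 0.115232
    factors: [{var: black, transform: identity}, {var: diabetes, transform: identity}]
  - coef: -0.092231
    factors: [{var: black, transform: identity}, {var: smoker, transform: identity}]
  - coef: 0.070498
    factors: [{var: black, transform: identity}, {var: tc_hdl_ratio, transform: identity}]
  - coef: -0.000173
    factors: [{var: black, transform: identity}, {var: sbp, transform: identity}, {var: bp_treated, transform: identity}]
  - coef: -0.000094
    factors: [{var: black, transform: identity}, {var: age, transform: identity}, {var: sbp, transform: identity}]
source: "Revised Pooled Cohort Equations refit on updated cohorts (logistic form, women); elastic-net logistic coefficient table of the revising publication. Recalibration constants not applied."
retrieved: "2026-09-29"
checksum: "n:19;sum:-9.189663"
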