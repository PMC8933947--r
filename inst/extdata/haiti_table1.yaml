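# Default synthetic-cohort marginal targets: the analytic sample of the Haiti
# CVD Cohort (adults >= 40 without prior CVD or statin use, n = 1345).
# Prevalences are proportions of the analytic sample; age in years, pressures
# in mmHg, lipids in mg/dL, BMI in kg/m2.
n: 1345
prop_female: 0.609
age: {min: 40, q25: 47, median: 54, q75: 62}
prevalence:
  diabetes: 0.078
  smoker_current: 0.040
  bp_treated: 0.187
  bmi_ge_30: 0.218
  hdl_lt_40: 0.210
  ldl_ge_130: 0.335
  sbp_ge_140: 0.398
  dbp_ge_90: 0.259
  hypertension: 0.529
continuous:
  # location/scale of latent marginal distributions solved from the cut-point
  # targets above (see the methods vignette for the derivations)
  sbp: {mean: 133.13, sd: 26.56}
  dbp: {mean: 79.11, sd: 16.84}
  hdl: {median: 50, sigma_log: 0.277}
  ldl: {median: 115, sigma_log: 0.288}
  vldl: {median: 25, sigma_log: 0.40}
  bmi: {median: 26.0, sigma_log: 0.1837}
  sbp_reading_sd: 4.0
latent_correlation:
  # modest positive dependence; a modelling choice, not a published structure
  age_sbp: 0.35
  age_dbp: 0.15
  age_ldl: 0.20
  sbp_dbp: 0.70
  bmi_sbp: 0.20
  bmi_diabetes: 0.25
  female_smoker: -0.30
  female_hdl: 0.15
  # solved so the derived hypertension prevalence (treatment OR SBP>=140 OR
  # DBP>=90) matches its target above
  treated_sbp: 0.30
  treated_dbp: 0.13
prevalence_extra:
  fam_hx_premature_chd: 0.05
  hiv: 0.025
prevalence_injected:
  prior_mi: 0.0
  prior_stroke: 0.0
  on_statin: 0.0
  age_lt_40: 0.0
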