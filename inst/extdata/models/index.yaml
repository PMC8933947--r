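# Registry index for the six 10-year CVD risk models.
# Order here is the canonical reporting order used throughout the package.
models:
  - id: pce
    label: "Pooled Cohort Equations (PCE)"
    form: cox
    strata:
      - {sex: female, ancestry: white, file: pce_female_white.yaml}
      - {sex: female, ancestry: black, file: pce_female_black.yaml}
      - {sex: male,   ancestry: white, file: pce_male_white.yaml}
      - {sex: male,   ancestry: black, file: pce_male_black.yaml}
  - id: apce
    label: "Adjusted PCE (revised, logistic form)"
    form: logistic
    strata:
      - {sex: female, file: apce_female.yaml}
      - {sex: male,   file: apce_male.yaml}
  - id: framingham_lipids
    label: "Framingham general CVD, lipid version"
    form: cox
    strata:
      - {sex: female, file: framingham_lipids_female.yaml}
      - {sex: male,   file: framingham_lipids_male.yaml}
  - id: framingham_bmi
    label: "Framingham general CVD, BMI (office-based) version"
    form: cox
    strata:
      - {sex: female, file: framingham_bmi_female.yaml}
      - {sex: male,   file: framingham_bmi_male.yaml}
  - id: who_lipids
    label: "WHO-style laboratory model (synthetic coefficients)"
    form: cox
    strata:
      - {sex: female, file: who_lipids_female.yaml}
      - {sex: male,   file: who_lipids_male.yaml}
  - id: who_bmi
    label: "WHO-style non-laboratory (BMI) model (synthetic coefficients)"
    form: cox
    strata:
      - {sex: female, file: who_bmi_female.yaml}
      - {sex: male,   file: who_bmi_male.yaml}
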