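# Participant-profile builders used across the suite.

make_profile <- function(id = "p1", age = 55, sex = "female", tc = 200,
                         hdl = 50, ldl = 120, sbp = 130, treated = 0,
                         diabetes = 0, smoker = 0, bmi = 26, dbp = 80,
                         prior_mi = 0, prior_stroke = 0, on_statin = 0,
                         fam_hx = 0) {
  data.frame(
    participant_id = id, age_years = age, sex = sex, tc_mgdl = tc,
    hdl_mgdl = hdl, ldl_mgdl = ldl, sbp1_mmhg = sbp, sbp2_mmhg = sbp,
    sbp3_mmhg = sbp, dbp_avg_mmhg = dbp, bp_treated = treated,
    diabetes = diabetes, smoker_current = smoker, bmi_kgm2 = bmi,
    prior_mi = prior_mi, prior_stroke = prior_stroke, on_statin = on_statin,
    fam_hx_premature_chd = fam_hx, hiv = 0,
    stringsAsFactors = FALSE
  )
}

# n random but physiologically plausible profiles, deterministic given seed
random_profiles <- function(n, seed = 42) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n), function(i) {
    make_profile(
      id = sprintf("r%04d", i),
      age = runif(1, 40, 79),
      sex = sample(c("female", "male"), 1),
      tc = runif(1, 130, 320),
      hdl = runif(1, 25, 90),
      ldl = runif(1, 60, 220),
      sbp = runif(1, 95, 195),
      treated = rbinom(1, 1, 0.3),
      diabetes = rbinom(1, 1, 0.2),
      smoker = rbinom(1, 1, 0.2),
      bmi = runif(1, 18, 42)
    )
  }))
}

# oracle input convenience: single averaged SBP column
with_sbp <- function(p) {
  p$sbp <- (p$sbp2_mmhg + p$sbp3_mmhg) / 2
  p
}

score_quiet <- function(...) suppressMessages(score_cohort(...))

# three fixed reference profiles per model family used in oracle checks
reference_profiles <- function() {
  rbind(
    make_profile("ref1", age = 55, sex = "male", tc = 213, hdl = 50,
                 ldl = 130, sbp = 120, treated = 0, smoker = 0, diabetes = 0,
                 bmi = 25),
    make_profile("ref2", age = 61, sex = "female", tc = 180, hdl = 47,
                 ldl = 110, sbp = 124, treated = 0, smoker = 1, diabetes = 0,
                 bmi = 29),
    make_profile("ref3", age = 70, sex = "male", tc = 250, hdl = 35,
                 ldl = 160, sbp = 160, treated = 1, smoker = 1, diabetes = 1,
                 bmi = 33),
    make_profile("ref4", age = 44, sex = "female", tc = 155, hdl = 62,
                 ldl = 85, sbp = 105, treated = 0, smoker = 0, diabetes = 0,
                 bmi = 21)
  )
}
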