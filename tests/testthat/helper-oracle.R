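# Independent minimal evaluators for every model: a second, separately typed
# transcription of each coefficient table, written as direct arithmetic.
# These never touch the package's YAML configs or the risk engine.

oracle_pce <- function(sex, ancestry, age, tc, hdl, sbp, treated, smoker,
                       diabetes) {
  la <- log(age); lt <- log(tc); lh <- log(hdl); ls <- log(sbp)
  lst <- ls * treated; lsu <- ls * (1 - treated)
  if (sex == "female" && ancestry == "white") {
    lp <- -29.799 * la + 4.884 * la^2 + 13.540 * lt - 3.114 * la * lt -
      13.578 * lh + 3.149 * la * lh + 2.019 * lst + 1.957 * lsu +
      7.574 * smoker - 1.665 * la * smoker + 0.661 * diabetes
    s0 <- 0.9665; ctr <- -29.18
  } else if (sex == "female" && ancestry == "black") {
    lp <- 17.114 * la + 0.940 * lt - 18.920 * lh + 4.475 * la * lh +
      29.291 * lst - 6.432 * la * lst + 27.820 * lsu - 6.087 * la * lsu +
      0.691 * smoker + 0.874 * diabetes
    s0 <- 0.9533; ctr <- 86.61
  } else if (sex == "male" && ancestry == "white") {
    lp <- 12.344 * la + 11.853 * lt - 2.664 * la * lt - 7.990 * lh +
      1.769 * la * lh + 1.797 * lst + 1.764 * lsu + 7.837 * smoker -
      1.795 * la * smoker + 0.658 * diabetes
    s0 <- 0.9144; ctr <- 61.18
  } else {
    lp <- 2.469 * la + 0.302 * lt - 0.307 * lh + 1.916 * lst + 1.809 * lsu +
      0.549 * smoker + 0.645 * diabetes
    s0 <- 0.8954; ctr <- 19.54
  }
  1 - s0^exp(lp - ctr)
}

oracle_apce <- function(sex, black, age, sbp, treated, diabetes, smoker,
                        tc, hdl) {
  r <- tc / hdl
  b <- as.numeric(black)
  if (sex == "female") {
    lp <- -12.823110 + 0.106501 * age + 0.432440 * b + 0.000056 * sbp^2 +
      0.017666 * sbp + 0.731678 * treated + 0.943970 * diabetes +
      1.009790 * smoker + 0.151318 * r - 0.008580 * age * b -
      0.003647 * sbp * treated + 0.006208 * sbp * b +
      0.152968 * b * treated - 0.000153 * age * sbp +
      0.115232 * b * diabetes - 0.092231 * b * smoker +
      0.070498 * b * r - 0.000173 * b * sbp * treated -
      0.000094 * b * age * sbp
  } else {
    lp <- -11.679980 + 0.064200 * age + 0.482835 * b - 0.000061 * sbp^2 +
      0.038950 * sbp + 2.055533 * treated + 0.842209 * diabetes +
      0.895589 * smoker + 0.193307 * r - 0.014207 * sbp * treated +
      0.011609 * sbp * b - 0.119460 * b * treated +
      0.000025 * age * sbp - 0.077214 * b * diabetes -
      0.226771 * b * smoker - 0.117749 * b * r +
      0.004190 * b * treated * sbp - 0.000199 * b * age * sbp
  }
  1 / (1 + exp(-lp))
}

oracle_framingham_lipids <- function(sex, age, tc, hdl, sbp, treated, smoker,
                                     diabetes) {
  ls <- log(sbp)
  if (sex == "female") {
    lp <- 2.32888 * log(age) + 1.20904 * log(tc) - 0.70833 * log(hdl) +
      2.76157 * ls * (1 - treated) + 2.82263 * ls * treated +
      0.52873 * smoker + 0.69154 * diabetes
    1 - 0.95012^exp(lp - 26.1931)
  } else {
    lp <- 3.06117 * log(age) + 1.12370 * log(tc) - 0.93263 * log(hdl) +
      1.93303 * ls * (1 - treated) + 1.99881 * ls * treated +
      0.65451 * smoker + 0.57367 * diabetes
    1 - 0.88936^exp(lp - 23.9802)
  }
}

oracle_framingham_bmi <- function(sex, age, bmi, sbp, treated, smoker,
                                  diabetes) {
  ls <- log(sbp)
  if (sex == "female") {
    lp <- 2.72107 * log(age) + 0.51125 * log(bmi) +
      2.81291 * ls * (1 - treated) + 2.88267 * ls * treated +
      0.61868 * smoker + 0.77763 * diabetes
    1 - 0.94833^exp(lp - 26.0145)
  } else {
    lp <- 3.11296 * log(age) + 0.79277 * log(bmi) +
      1.85508 * ls * (1 - treated) + 1.92672 * ls * treated +
      0.70953 * smoker + 0.53160 * diabetes
    1 - 0.88431^exp(lp - 23.9388)
  }
}

oracle_who_lipids <- function(sex, age, sbp, tc_mgdl, diabetes, smoker) {
  tc <- tc_mgdl / 38.67
  if (sex == "female") {
    lp <- 0.075 * age + 0.014 * sbp + 0.12 * tc + 0.70 * diabetes +
      0.60 * smoker
    1 - 0.95^exp(lp - 6.85)
  } else {
    lp <- 0.080 * age + 0.013 * sbp + 0.14 * tc + 0.65 * diabetes +
      0.65 * smoker
    1 - 0.93^exp(lp - 7.125)
  }
}

oracle_who_bmi <- function(sex, age, sbp, bmi, smoker) {
  if (sex == "female") {
    lp <- 0.075 * age + 0.014 * sbp + 0.045 * bmi + 0.60 * smoker
    1 - 0.95^exp(lp - 7.42)
  } else {
    lp <- 0.080 * age + 0.013 * sbp + 0.050 * bmi + 0.65 * smoker
    1 - 0.93^exp(lp - 7.725)
  }
}

# risk for one profile row under any model id, via the oracles above
oracle_risk <- function(model_id, p, ancestry = "black") {
  switch(model_id,
    pce = oracle_pce(p$sex, ancestry, p$age_years, p$tc_mgdl, p$hdl_mgdl,
                     p$sbp, p$bp_treated, p$smoker_current, p$diabetes),
    apce = oracle_apce(p$sex, ancestry == "black", p$age_years, p$sbp,
                       p$bp_treated, p$diabetes, p$smoker_current,
                       p$tc_mgdl, p$hdl_mgdl),
    framingham_lipids = oracle_framingham_lipids(
      p$sex, p$age_years, p$tc_mgdl, p$hdl_mgdl, p$sbp, p$bp_treated,
      p$smoker_current, p$diabetes),
    framingham_bmi = oracle_framingham_bmi(
      p$sex, p$age_years, p$bmi_kgm2, p$sbp, p$bp_treated,
      p$smoker_current, p$diabetes),
    who_lipids = oracle_who_lipids(p$sex, p$age_years, p$sbp, p$tc_mgdl,
                                   p$diabetes, p$smoker_current),
    who_bmi = oracle_who_bmi(p$sex, p$age_years, p$sbp, p$bmi_kgm2,
                             p$smoker_current),
    stop("no oracle for ", model_id)
  )
}
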