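flagged <- function(p) {
  p$sbp_avg_mmhg <- average_bp(p$sbp1_mmhg, p$sbp2_mmhg, p$sbp3_mmhg)
  suppressWarnings(derive_flags(p))
}

test_that("PCE-family criteria fire individually and in printed order", {
  d <- statin_eligible_pce_family(make_profile(ldl = 200, diabetes = 0), 0.01)
  expect_true(d$eligible); expect_equal(d$criterion, "pce_1")
  d <- statin_eligible_pce_family(make_profile(ldl = 80, diabetes = 1), 0.02)
  expect_true(d$eligible); expect_equal(d$criterion, "pce_2")
  d <- statin_eligible_pce_family(make_profile(ldl = 80, diabetes = 0), 0.08)
  expect_true(d$eligible); expect_equal(d$criterion, "pce_3")
  # all criteria need LDL >= 70 (or 190): high risk alone is not enough
  d <- statin_eligible_pce_family(make_profile(ldl = 60, diabetes = 0), 0.30)
  expect_false(d$eligible); expect_true(is.na(d$criterion))
  # first-hit attribution: LDL 200 + diabetes reports criterion 1
  d <- statin_eligible_pce_family(make_profile(ldl = 200, diabetes = 1), 0.2)
  expect_equal(d$criterion, "pce_1")
  expect_error(
    statin_eligible_pce_family(make_profile(ldl = NA), 0.1), "LDL"
  )
})

test_that("Framingham risk-factor count enumerates the sex-specific list", {
  m <- flagged(make_profile(sex = "male", age = 50, smoker = 1, hdl = 35,
                            sbp = 120, fam_hx = 0))
  expect_equal(count_framingham_risk_factors(m), 3L) # smoker, HDL, male age
  f <- flagged(make_profile(sex = "female", age = 50))
  expect_equal(count_framingham_risk_factors(f), 0L) # female cut is 55
  # all factors, male: smoking + htn + HDL + fam hx + age = 5 (cap)
  allm <- flagged(make_profile(sex = "male", age = 60, smoker = 1, hdl = 30,
                               sbp = 150, fam_hx = 1))
  expect_equal(count_framingham_risk_factors(allm), 5L)
  allf <- flagged(make_profile(sex = "female", age = 60, smoker = 1, hdl = 30,
                               sbp = 150, fam_hx = 1))
  expect_equal(count_framingham_risk_factors(allf), 5L)
})

test_that("each Framingham criterion fires on a profile built for it alone", {
  base <- function(...) flagged(make_profile(sex = "male", age = 40, ...))
  cases <- list(
    list(p = base(ldl = 195, hdl = 60, diabetes = 0), risk = 0.05,
         crit = "fram_1"),
    list(p = base(ldl = 110, hdl = 60, diabetes = 1), risk = 0.05,
         crit = "fram_2"),
    list(p = base(ldl = 110, hdl = 60, diabetes = 0), risk = 0.25,
         crit = "fram_3"),
    list(p = base(ldl = 135, hdl = 35, smoker = 1, diabetes = 0), risk = 0.15,
         crit = "fram_4"),
    list(p = base(ldl = 165, hdl = 35, smoker = 1, diabetes = 0), risk = 0.05,
         crit = "fram_5")
  )
  for (cs in cases) {
    d <- statin_eligible_framingham(cs$p, cs$risk)
    expect_true(d$eligible, label = cs$crit)
    expect_equal(d$criterion, cs$crit)
    # and only that criterion fires on this profile
    others <- setdiff(paste0("fram_", 1:5), cs$crit)
    expect_false(d$criterion %in% others)
  }
  # criterion 5 needs >= 2 risk factors
  d <- statin_eligible_framingham(base(ldl = 165, hdl = 60, smoker = 1,
                                       diabetes = 0), 0.05)
  expect_false(d$eligible)
})

test_that("Framingham band edges route to the right criterion", {
  p <- flagged(make_profile(sex = "male", age = 40, ldl = 135, hdl = 35,
                            smoker = 1, diabetes = 0))
  expect_equal(statin_eligible_framingham(p, 0.0999)$criterion, NA_character_)
  expect_equal(statin_eligible_framingham(p, 0.10)$criterion, "fram_4")
  expect_equal(statin_eligible_framingham(p, 0.1999)$criterion, "fram_4")
  expect_equal(statin_eligible_framingham(p, 0.20)$criterion, "fram_3")
})

test_that("WHO eligibility is the 20% risk threshold, boundary inclusive", {
  d <- statin_eligible_who(c(0.21, 0.19, 0.20))
  expect_equal(d$eligible, c(TRUE, FALSE, TRUE))
  expect_equal(d$criterion, c("who_1", NA, "who_1"))
})

test_that("eligibility never flips off as risk rises (monotone in risk)", {
  risks <- seq(0, 0.6, by = 0.01)
  p <- flagged(make_profile(sex = "male", age = 50, ldl = 135, hdl = 35,
                            smoker = 1))
  for (fn in list(
    function(r) statin_eligible_pce_family(p[rep(1, length(r)), ], r)$eligible,
    function(r) statin_eligible_framingham(p[rep(1, length(r)), ], r)$eligible,
    function(r) statin_eligible_who(r)$eligible
  )) {
    e <- fn(risks)
    expect_true(all(diff(as.integer(e)) >= 0))
  }
})

test_that("WHO statin eligibility coincides exactly with the WHO high category", {
  cohort <- random_profiles(80, seed = 23)
  sample <- flagged(cohort)
  scores <- score_quiet(sample, c("who_lipids", "who_bmi"))
  cats <- categorize_cohort(scores, "model_specific")
  decisions <- statin_decisions(sample, scores)
  merged <- merge(decisions, cats, by = c("participant_id", "model_id"))
  expect_identical(merged$eligible, merged$category == "high")
})

test_that("PCE high-category participants with LDL >= 70 are always eligible", {
  cohort <- random_profiles(80, seed = 29)
  sample <- flagged(cohort)
  scores <- score_quiet(sample, "pce")
  cats <- categorize_cohort(scores, "model_specific")
  dec <- statin_decisions(sample, scores)
  high_ids <- cats$participant_id[cats$category == "high"]
  ldl70 <- sample$participant_id[sample$ldl_mgdl >= 70]
  must <- intersect(high_ids, ldl70)
  expect_true(all(dec$eligible[dec$participant_id %in% must]))
})

test_that("eligibility table matches brute-force per-participant evaluation", {
  cohort <- random_profiles(60, seed = 31)
  sample <- flagged(cohort)
  scores <- score_quiet(sample)
  dec <- statin_decisions(sample, scores)
  tab <- eligibility_table(dec)
  expect_equal(tab$model_id, c("pce", "apce", "framingham_lipids",
                               "framingham_bmi", "who_lipids", "who_bmi"))
  for (m in tab$model_id) {
    sc <- scores[scores$model_id == m, ]
    brute <- 0
    for (i in seq_len(nrow(sc))) {
      p <- sample[sample$participant_id == sc$participant_id[i], ]
      r <- sc$risk10y[i]
      e <- switch(cvdcompare:::.statin_family[[m]],
        pce = statin_eligible_pce_family(p, r)$eligible,
        framingham = statin_eligible_framingham(p, r)$eligible,
        who = statin_eligible_who(r)$eligible
      )
      brute <- brute + e
    }
    expect_equal(tab$eligible[tab$model_id == m], brute)
    expect_true(tab$ci_lower[tab$model_id == m] <=
                  tab$prop[tab$model_id == m])
    expect_true(tab$ci_upper[tab$model_id == m] >=
                  tab$prop[tab$model_id == m])
  }
})
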