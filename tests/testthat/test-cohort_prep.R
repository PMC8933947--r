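test_that("BP averaging uses readings 2 and 3 and ignores reading 1", {
  expect_equal(average_bp(150, 120, 130), 125)
  expect_equal(average_bp(100, 131, 132), 131.5)
  expect_equal(average_bp(90, 117, 117), 117)   # identity when 2 == 3
  expect_equal(average_bp(c(150, 100), c(120, 131), c(130, 132)),
               c(125, 131.5))
  expect_true(is.na(average_bp(120, NA, 130)))
})

write_cohort_fixture <- function(df) {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE)
  f
}

test_that("read_cohort accepts valid rows and rejects invalid ones with reasons", {
  good <- do.call(rbind, lapply(1:5, function(i) make_profile(paste0("p", i))))
  res <- read_cohort(write_cohort_fixture(good))
  expect_equal(nrow(res$records), 5)
  expect_equal(nrow(res$rejected), 0)
  expect_equal(res$records$sbp_avg_mmhg, rep(130, 5))

  bad <- good
  bad$sbp2_mmhg[2] <- -5
  bad$sex[4] <- "F"
  res <- read_cohort(write_cohort_fixture(bad))
  expect_equal(nrow(res$records), 3)
  expect_equal(res$rejected$row, c(2L, 4L))
  expect_match(res$rejected$reason[1], "sbp2")
  expect_match(res$rejected$reason[2], "sex")
})

test_that("read_cohort converts mmol/L lipid columns to mg/dL on load", {
  p <- make_profile("p1", tc = 200, hdl = 50, ldl = 120)
  mm <- p
  mm$tc_mmoll <- convert_units(p$tc_mgdl, "mg/dL", "mmol/L")
  mm$hdl_mmoll <- convert_units(p$hdl_mgdl, "mg/dL", "mmol/L")
  mm$ldl_mmoll <- convert_units(p$ldl_mgdl, "mg/dL", "mmol/L")
  mm$tc_mgdl <- mm$hdl_mgdl <- mm$ldl_mgdl <- NULL
  res <- read_cohort(write_cohort_fixture(mm))
  expect_equal(res$records$tc_mgdl, 200, tolerance = 1e-9)
  expect_equal(res$records$hdl_mgdl, 50, tolerance = 1e-9)
  expect_equal(res$records$ldl_mgdl, 120, tolerance = 1e-9)
})

test_that("read_cohort fails on missing columns and warns on unknown ones", {
  p <- make_profile()
  p$age_years <- NULL
  expect_error(read_cohort(write_cohort_fixture(p)), "age_years")
  p <- make_profile()
  p$shoe_size <- 42
  expect_warning(read_cohort(write_cohort_fixture(p)), "shoe_size")
})

test_that("inclusion cascade excludes sequentially with first-failure attribution", {
  recs <- rbind(
    make_profile("keep1"),
    make_profile("young_statin", age = 35, on_statin = 1), # counted at age step
    make_profile("keep2", age = 41),
    make_profile("statin", on_statin = 1),
    make_profile("stroke", prior_stroke = 1),
    make_profile("keep3", age = 70)
  )
  recs$sbp_avg_mmhg <- 130
  incomplete <- make_profile("noLipid")
  incomplete$tc_mgdl <- NA
  incomplete$sbp_avg_mmhg <- 130
  recs <- rbind(recs, incomplete)

  res <- apply_inclusion_filters(recs)
  r <- res$report
  expect_equal(r$incomplete, 1)
  expect_equal(r$age_lt_40, 1)      # the under-40 statin user lands here
  expect_equal(r$on_statin, 1)
  expect_equal(r$prior_mi_stroke, 1)
  expect_equal(r$final_n, 3)
  expect_equal(res$sample$participant_id, c("keep1", "keep2", "keep3"))
  # counts reconcile
  expect_equal(r$input_n - r$incomplete - r$age_lt_40 - r$on_statin -
                 r$prior_mi_stroke, r$final_n)
})

test_that("inclusion filtering is idempotent and order-equivariant", {
  recs <- random_profiles(40, seed = 11)
  recs$on_statin[c(3, 9)] <- 1
  recs$prior_mi[c(5, 9)] <- 1
  recs$age_years[7] <- 32
  recs$sbp_avg_mmhg <- (recs$sbp2_mmhg + recs$sbp3_mmhg) / 2

  once <- apply_inclusion_filters(recs)
  twice <- apply_inclusion_filters(once$sample)
  expect_equal(twice$sample, once$sample)
  expect_equal(twice$report$final_n, once$report$final_n)
  expect_equal(sum(unlist(twice$report[c("incomplete", "age_lt_40",
                                         "on_statin", "prior_mi_stroke")])), 0)

  perm <- sample(nrow(recs))
  shuffled <- apply_inclusion_filters(recs[perm, ])
  expect_setequal(shuffled$sample$participant_id, once$sample$participant_id)
  expect_equal(shuffled$report[-1], once$report[-1])

  empty <- apply_inclusion_filters(recs[0, ])
  expect_equal(empty$report$final_n, 0)
  expect_equal(nrow(empty$sample), 0)
})

test_that("derived flags implement the hypertension definition and SBP split", {
  r1 <- make_profile("a", sbp = 145, treated = 0, dbp = 80)
  r2 <- make_profile("b", sbp = 120, treated = 0, dbp = 80)
  r3 <- make_profile("c", sbp = 120, treated = 1, dbp = 80)
  r4 <- make_profile("d", sbp = 120, treated = 0, dbp = 95)
  recs <- rbind(r1, r2, r3, r4)
  recs$sbp_avg_mmhg <- average_bp(recs$sbp1_mmhg, recs$sbp2_mmhg,
                                  recs$sbp3_mmhg)
  out <- derive_flags(recs)
  expect_equal(out$hypertension, c(1, 0, 1, 1))
  expect_equal(out$sbp_untreated, c(145, 120, NA, 120))
  expect_equal(out$sbp_treated, c(NA, NA, 120, NA))
})

test_that("missing family history defaults to absent with a warning", {
  r <- make_profile()
  r$fam_hx_premature_chd <- NA
  r$sbp_avg_mmhg <- 130
  expect_warning(out <- derive_flags(r), "family history")
  expect_equal(out$fam_hx_premature_chd, 0)
})
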