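# Statin-eligibility decision rules, one family per model group.
# Eligibility is a disjunction; criteria are evaluated in their published
# order and the first criterion that fires is recorded as reporting metadata.

#' Statin eligibility under the PCE-family rule
#'
#' Eligible iff (1) LDLc >= 190 mg/dL, or (2) diabetes and LDLc >= 70 mg/dL,
#' or (3) 10-year CVD risk >= 7.5% and LDLc >= 70 mg/dL.
#'
#' @param records data.frame with `ldl_mgdl` and `diabetes`.
#' @param risk Numeric vector of 10-year risks from the PCE or adjusted PCE.
#' @return data.frame `eligible` (logical), `criterion` (`"pce_1"`..`"pce_3"`
#'   or `NA`).
#' @export
statin_eligible_pce_family <- function(records, risk) {
  ldl <- records$ldl_mgdl
  if (anyNA(ldl)) stop("LDL cholesterol missing; cannot apply statin rule",
                       call. = FALSE)
  c1 <- ldl >= 190
  c2 <- records$diabetes == 1 & ldl >= 70
  c3 <- risk >= 0.075 & ldl >= 70
  first_hit(list(pce_1 = c1, pce_2 = c2, pce_3 = c3))
}

#' Count Framingham treatment-rule risk factors
#'
#' The six factors: current smoking; hypertension; HDLc < 40 mg/dL; MI or
#' angina in a first-degree relative before age 50; age >= 45 (men); age >= 55
#' (women). The two age criteria are sex-specific, so at most one can
#' contribute and the count is 0..5.
#'
#' @param records data.frame with `derive_flags()` applied (`hypertension`,
#'   `fam_hx_premature_chd` present).
#' @return Integer vector of risk-factor counts.
#' @export
count_framingham_risk_factors <- function(records) {
  fam <- records$fam_hx_premature_chd
  if (anyNA(fam)) {
    warning("missing family history counted as absent", call. = FALSE)
    fam[is.na(fam)] <- 0
  }
  age_factor <- ifelse(records$sex == "male",
                       records$age_years >= 45,
                       records$age_years >= 55)
  as.integer(records$smoker_current == 1) +
    as.integer(records$hypertension == 1) +
    as.integer(records$hdl_mgdl < 40) +
    as.integer(fam == 1) +
    as.integer(age_factor)
}

#' Statin eligibility under the Framingham-family rule
#'
#' Eligible iff (1) LDLc >= 190, or (2) diabetes and LDLc >= 100, or (3) risk
#' >= 20% and LDLc >= 100, or (4) risk in \[10%, 20%) and LDLc >= 130 with
#' >= 2 risk factors, or (5) risk < 10% and LDLc >= 160 with >= 2 risk
#' factors. Criterion 4's risk band is half-open so criteria 3-5 partition
#' the risk axis.
#'
#' @param records data.frame with `derive_flags()` applied.
#' @param risk Numeric vector of 10-year risks from a Framingham model.
#' @return data.frame `eligible`, `criterion` (`"fram_1"`..`"fram_5"` or `NA`).
#' @export
statin_eligible_framingham <- function(records, risk) {
  ldl <- records$ldl_mgdl
  if (anyNA(ldl)) stop("LDL cholesterol missing; cannot apply statin rule",
                       call. = FALSE)
  rf <- count_framingham_risk_factors(records)
  c1 <- ldl >= 190
  c2 <- records$diabetes == 1 & ldl >= 100
  c3 <- risk >= 0.20 & ldl >= 100
  c4 <- risk >= 0.10 & risk < 0.20 & ldl >= 130 & rf >= 2
  c5 <- risk < 0.10 & ldl >= 160 & rf >= 2
  first_hit(list(fram_1 = c1, fram_2 = c2, fram_3 = c3, fram_4 = c4,
                 fram_5 = c5))
}

#' Statin eligibility under the WHO rule
#'
#' Eligible iff 10-year CVD risk >= 20%. By construction this coincides
#' exactly with the WHO models' high category under model-specific
#' thresholds.
#'
#' @param risk Numeric vector of 10-year risks from a WHO model.
#' @return data.frame `eligible`, `criterion` (`"who_1"` or `NA`).
#' @export
statin_eligible_who <- function(risk) {
  first_hit(list(who_1 = risk >= 0.20))
}

first_hit <- function(criteria) {
  n <- length(criteria[[1]])
  crit <- rep(NA_character_, n)
  for (nm in rev(names(criteria))) crit[criteria[[nm]]] <- nm
  data.frame(eligible = !is.na(crit), criterion = crit,
             stringsAsFactors = FALSE)
}

.statin_family <- c(
  pce = "pce", apce = "pce",
  framingham_lipids = "framingham", framingham_bmi = "framingham",
  who_lipids = "who", who_bmi = "who"
)

#' Statin decisions for a scored cohort
#'
#' Dispatches each model's scores to its rule family (PCE family for pce and
#' apce; Framingham family for the two Framingham models; the WHO risk
#' threshold for the WHO models). Participants already on statins are assumed
#' excluded upstream by [apply_inclusion_filters()].
#'
#' @param records Analytic sample with [derive_flags()] applied.
#' @param scores data.frame from [score_cohort()].
#' @return Tidy data.frame `participant_id`, `model_id`, `eligible`,
#'   `criterion`.
#' @export
statin_decisions <- function(records, scores) {
  records <- as.data.frame(records)
  out <- lapply(split(scores, scores$model_id), function(sc) {
    fam <- .statin_family[[sc$model_id[1]]]
    if (is.null(fam)) stop("no statin rule family for model ",
                           sc$model_id[1], call. = FALSE)
    d <- records[match(sc$participant_id, records$participant_id), ,
                 drop = FALSE]
    dec <- switch(fam,
      pce = statin_eligible_pce_family(d, sc$risk10y),
      framingham = statin_eligible_framingham(d, sc$risk10y),
      who = statin_eligible_who(sc$risk10y)
    )
    cbind(sc[c("participant_id", "model_id")], dec)
  })
  res <- do.call(rbind, out)
  # restore registry model order, then input participant order
  res <- res[order(match(res$model_id, .cvd_model_ids),
                   match(res$participant_id, records$participant_id)), ]
  rownames(res) <- NULL
  res
}

#' Per-model statin-eligible counts with Wilson intervals
#'
#' @param decisions data.frame from [statin_decisions()].
#' @param level Confidence level for the Wilson score interval.
#' @return data.frame `model_id`, `n`, `eligible`, `prop`, `ci_lower`,
#'   `ci_upper`.
#' @export
eligibility_table <- function(decisions, level = 0.95) {
  out <- lapply(split(decisions, decisions$model_id), function(d) {
    x <- sum(d$eligible)
    n <- nrow(d)
    ci <- wilson_ci(x, n, level)
    data.frame(model_id = d$model_id[1], n = n, eligible = x, prop = x / n,
               ci_lower = ci[1], ci_upper = ci[2], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(match(res$model_id, .cvd_model_ids)), ]
  rownames(res) <- NULL
  res
}
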