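# Cohort ingestion: BP averaging, inclusion cascade, derived flags.

# Canonical cohort CSV schema, version 1. Booleans as 0/1.
.cohort_required_cols <- c(
  "participant_id", "age_years", "sex", "tc_mgdl", "hdl_mgdl", "ldl_mgdl",
  "sbp1_mmhg", "sbp2_mmhg", "sbp3_mmhg", "bp_treated", "diabetes",
  "smoker_current", "bmi_kgm2", "prior_mi", "prior_stroke", "on_statin"
)
.cohort_optional_cols <- c("dbp_avg_mmhg", "fam_hx_premature_chd", "hiv")

#' Average seated blood-pressure readings
#'
#' Of three seated readings taken at one-minute intervals, the first is
#' discarded and the second and third are averaged; the average is the SBP (or
#' DBP) used in all downstream analyses.
#'
#' @param reading1,reading2,reading3 Numeric vectors, mmHg. `reading1` is
#'   accepted for interface completeness and ignored.
#' @return `(reading2 + reading3) / 2`; `NA` where either is missing.
#' @examples
#' average_bp(150, 120, 130) # 125
#' @export
average_bp <- function(reading1, reading2, reading3) {
  (reading2 + reading3) / 2
}

#' Read a participant-level cohort file
#'
#' Reads the documented delimited cohort schema, validates each row against
#' the participant-record invariants (positive age, strictly positive
#' concentrations and pressures, parseable 0/1 flags), computes the averaged
#' SBP from readings 2 and 3, and converts lipid columns supplied in mmol/L
#' (`tc_mmoll`, `hdl_mmoll`, `ldl_mmoll`) to the internal mg/dL.
#'
#' @param path Delimited text file with a header row.
#' @param sep Field separator (default comma).
#' @return List with `records` (validated data.frame, one row per accepted
#'   participant, lipids in mg/dL, plus derived `sbp_avg_mmhg`) and
#'   `rejected` (data.frame of row number and reason).
#' @export
read_cohort <- function(path, sep = ",") {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  # mmol/L lipid variants are accepted and converted on load
  mm_map <- c(tc_mmoll = "tc_mgdl", hdl_mmoll = "hdl_mgdl",
              ldl_mmoll = "ldl_mgdl")
  for (mm in names(mm_map)) {
    if (mm %in% names(raw) && !(mm_map[[mm]] %in% names(raw))) {
      raw[[mm_map[[mm]]]] <- convert_units(as.numeric(raw[[mm]]),
                                           "mmol/L", "mg/dL")
      raw[[mm]] <- NULL
    }
  }
  missing_cols <- setdiff(.cohort_required_cols, names(raw))
  if (length(missing_cols) > 0) {
    stop("cohort file missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(raw), c(.cohort_required_cols, .cohort_optional_cols))
  if (length(unknown) > 0) {
    warning("ignoring unknown cohort columns: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (opt in .cohort_optional_cols) if (!opt %in% names(raw)) raw[[opt]] <- NA
  raw <- raw[c(.cohort_required_cols, .cohort_optional_cols)]

  reasons <- character(nrow(raw))
  num_pos <- c("age_years", "tc_mgdl", "hdl_mgdl", "ldl_mgdl",
               "sbp1_mmhg", "sbp2_mmhg", "sbp3_mmhg", "bmi_kgm2")
  for (cl in num_pos) {
    v <- suppressWarnings(as.numeric(raw[[cl]]))
    bad <- !is.na(raw[[cl]]) & (is.na(v) | v <= 0)
    reasons[bad & reasons == ""] <- paste0("non-positive or unparseable ", cl)
    raw[[cl]] <- v
  }
  for (cl in c("bp_treated", "diabetes", "smoker_current", "prior_mi",
               "prior_stroke", "on_statin", "fam_hx_premature_chd", "hiv")) {
    v <- suppressWarnings(as.numeric(raw[[cl]]))
    bad <- !is.na(raw[[cl]]) & !(v %in% c(0, 1))
    reasons[bad & reasons == ""] <- paste0("flag ", cl, " not 0/1")
    raw[[cl]] <- v
  }
  bad_sex <- !raw$sex %in% c("female", "male")
  reasons[bad_sex & reasons == ""] <- "sex not 'female'/'male'"

  keep <- reasons == ""
  rejected <- data.frame(row = which(!keep), reason = reasons[!keep],
                         stringsAsFactors = FALSE)
  records <- raw[keep, , drop = FALSE]
  records$sbp_avg_mmhg <- average_bp(records$sbp1_mmhg, records$sbp2_mmhg,
                                     records$sbp3_mmhg)
  rownames(records) <- NULL
  list(records = records, rejected = rejected)
}

model_input_cols <- c("age_years", "sex", "tc_mgdl", "hdl_mgdl", "ldl_mgdl",
                      "sbp2_mmhg", "sbp3_mmhg", "bp_treated", "diabetes",
                      "smoker_current", "bmi_kgm2")

#' Apply the analytic-sample inclusion cascade
#'
#' Exclusions are sequential with first-failure attribution, mirroring the
#' mutually exclusive exclusion counts of a cohort flow diagram: (1) incomplete
#' model inputs, (2) age < 40 years, (3) already on a statin, (4) history of
#' myocardial infarction or stroke. A record failing several criteria is
#' counted once, at the first failing step.
#'
#' @param records data.frame from [read_cohort()] (or [generate_cohort()]).
#' @return List with `sample` (the analytic sample) and `report`
#'   (`cvd_exclusion_report`: per-step counts that reconcile with input and
#'   output sizes).
#' @export
apply_inclusion_filters <- function(records) {
  n_in <- nrow(records)
  if (n_in == 0) {
    rep0 <- structure(list(input_n = 0L, incomplete = 0L, age_lt_40 = 0L,
                           on_statin = 0L, prior_mi_stroke = 0L, final_n = 0L),
                      class = "cvd_exclusion_report")
    return(list(sample = records, report = rep0))
  }
  incomplete <- rowSums(is.na(records[model_input_cols])) > 0
  age_lt_40 <- !incomplete & records$age_years < 40
  on_statin <- !incomplete & !age_lt_40 & records$on_statin == 1
  prior_cvd <- !incomplete & !age_lt_40 & !on_statin &
    (records$prior_mi == 1 | records$prior_stroke == 1)
  keep <- !(incomplete | age_lt_40 | on_statin | prior_cvd)
  report <- structure(
    list(input_n = n_in,
         incomplete = sum(incomplete),
         age_lt_40 = sum(age_lt_40),
         on_statin = sum(on_statin),
         prior_mi_stroke = sum(prior_cvd),
         final_n = sum(keep)),
    class = "cvd_exclusion_report"
  )
  sample <- records[keep, , drop = FALSE]
  rownames(sample) <- NULL
  list(sample = sample, report = report)
}

#' @export
print.cvd_exclusion_report <- function(x, ...) {
  cat("<cvd_exclusion_report>\n",
      "  enrolled:            ", x$input_n, "\n",
      "  - incomplete data:   ", x$incomplete, "\n",
      "  - age < 40:          ", x$age_lt_40, "\n",
      "  - on statin:         ", x$on_statin, "\n",
      "  - prior MI/stroke:   ", x$prior_mi_stroke, "\n",
      "  analytic sample:     ", x$final_n, "\n", sep = "")
  invisible(x)
}

#' Derive hypertension and treated/untreated SBP covariates
#'
#' Hypertension (used for risk-factor counting) is antihypertensive treatment
#' OR averaged SBP >= 140 mmHg OR averaged DBP >= 90 mmHg (DBP contributes only
#' when recorded). The treated/untreated SBP split produces the two mutually
#' exclusive covariates the risk equations consume: `sbp_treated` is the
#' averaged SBP when on treatment and `NA` otherwise, symmetrically for
#' `sbp_untreated`. Missing family history is set to absent with a warning.
#'
#' @param records data.frame with `sbp_avg_mmhg` present (see [read_cohort()]).
#' @return `records` with columns `hypertension`, `sbp_treated`,
#'   `sbp_untreated` added and `fam_hx_premature_chd` completed.
#' @export
derive_flags <- function(records) {
  if (is.null(records$sbp_avg_mmhg)) {
    stop("averaged SBP missing; run read_cohort()/average_bp() first",
         call. = FALSE)
  }
  dbp_high <- !is.na(records$dbp_avg_mmhg) & records$dbp_avg_mmhg >= 90
  records$hypertension <- as.integer(
    records$bp_treated == 1 | records$sbp_avg_mmhg >= 140 | dbp_high
  )
  records$sbp_treated <- ifelse(records$bp_treated == 1,
                                records$sbp_avg_mmhg, NA_real_)
  records$sbp_untreated <- ifelse(records$bp_treated == 1,
                                  NA_real_, records$sbp_avg_mmhg)
  if (anyNA(records$fam_hx_premature_chd)) {
    warning("family history of premature MI/angina missing for ",
            sum(is.na(records$fam_hx_premature_chd)),
            " record(s); treated as absent", call. = FALSE)
    records$fam_hx_premature_chd[is.na(records$fam_hx_premature_chd)] <- 0
  }
  records
}
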