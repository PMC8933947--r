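# Between-model comparison statistics: Spearman concordance, chi-square
# tests of independence, Wilson proportion intervals, and the risk-factor
# profile of each model's high-risk group.

#' Pairwise Spearman rank concordance between models
#'
#' Spearman correlations (average ranks for ties) between every pair of
#' models' continuous risk scores, measuring agreement in how the models rank
#' participants from lowest to highest risk.
#'
#' @param scores Either the tidy score table from [score_cohort()] or a wide
#'   numeric matrix/data.frame participants x models.
#' @return Symmetric correlation matrix with unit diagonal, models in registry
#'   order. A constant score column yields `NA` against every other column
#'   (coefficient undefined), with a warning.
#' @export
spearman_matrix <- function(scores) {
  wide <- if (is.data.frame(scores) && all(c("participant_id", "model_id",
                                             "risk10y") %in% names(scores))) {
    scores_to_wide(scores)
  } else {
    as.matrix(scores)
  }
  if (nrow(wide) < 3) stop("need at least 3 participants", call. = FALSE)
  if (anyNA(wide)) stop("missing scores in Spearman input", call. = FALSE)
  constant <- apply(wide, 2, function(x) length(unique(x)) == 1)
  if (any(constant)) {
    warning("constant score column(s): ",
            paste(colnames(wide)[constant], collapse = ", "),
            "; Spearman undefined (NA)", call. = FALSE)
  }
  m <- suppressWarnings(stats::cor(wide, method = "spearman"))
  diag(m) <- 1
  m
}

scores_to_wide <- function(scores) {
  wide <- stats::reshape(
    scores[c("participant_id", "model_id", "risk10y")],
    idvar = "participant_id", timevar = "model_id", direction = "wide"
  )
  rownames(wide) <- wide$participant_id
  wide$participant_id <- NULL
  colnames(wide) <- sub("^risk10y\\.", "", colnames(wide))
  as.matrix(wide[, sort_models(colnames(wide)), drop = FALSE])
}

#' Pearson chi-square test of independence
#'
#' Pearson chi-square without continuity correction, df = (rows-1)(cols-1).
#'
#' @param tab Numeric matrix of non-negative counts with positive row sums.
#' @return List `statistic`, `df`, `p_value`.
#' @export
chi_square_independence <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("negative cell count", call. = FALSE)
  if (any(rowSums(tab) == 0)) stop("zero row sum", call. = FALSE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) {
    bad <- which(expected == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("zero expected count in cell (%d, %d)", bad[1], bad[2]),
         call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' Wilson score interval for a binomial proportion
#'
#' The score-test (Wilson) interval without continuity correction, the
#' interval of the one-sample proportions test.
#'
#' @param successes,n Non-negative counts, `successes <= n`, `n > 0`.
#' @param level Confidence level (default 0.95).
#' @return `c(lower, upper)`, both in \[0, 1\].
#' @examples
#' round(wilson_ci(24, 1345), 3) # 0.012 0.026
#' @export
wilson_ci <- function(successes, n, level = 0.95) {
  stopifnot(n > 0, successes >= 0, successes <= n)
  # prop.test's CI with correct = FALSE is exactly the Wilson score interval
  ci <- stats::prop.test(successes, n, conf.level = level,
                         correct = FALSE)$conf.int
  c(lower = ci[1], upper = ci[2])
}

#' Risk-factor profile of each model's high-risk group
#'
#' For each model, restricts to participants the model categorizes as high
#' risk and summarizes their risk factors: median \[25th, 75th percentile\]
#' for age, SBP (split by treatment status), total cholesterol and HDL
#' (quantile type 7, linear interpolation), and n (%) for female, diabetes,
#' and current smoking.
#'
#' @param records Analytic sample with [derive_flags()] applied.
#' @param categories Tidy category data.frame for a single scheme.
#' @return data.frame, one row per model in registry order; an empty
#'   high-risk group yields `NA` summaries and `n_high = 0`.
#' @export
high_risk_profile_summary <- function(records, categories) {
  if (length(unique(categories$scheme)) > 1) {
    stop("summaries are per scheme; filter categories first", call. = FALSE)
  }
  records <- as.data.frame(records)
  med_iqr <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(c(NA_real_, NA_real_, NA_real_))
    stats::quantile(x, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  }
  models <- sort_models(unique(categories$model_id))
  rows <- lapply(models, function(m) {
    ids <- categories$participant_id[categories$model_id == m &
                                       categories$category == "high"]
    d <- records[records$participant_id %in% ids, , drop = FALSE]
    n <- nrow(d)
    a <- med_iqr(d$age_years)
    st <- med_iqr(d$sbp_treated)
    su <- med_iqr(d$sbp_untreated)
    tc <- med_iqr(d$tc_mgdl)
    hd <- med_iqr(d$hdl_mgdl)
    data.frame(
      model_id = m, n_high = n,
      prop_high = n / length(unique(categories$participant_id)),
      female_n = sum(d$sex == "female"),
      female_pct = if (n > 0) 100 * mean(d$sex == "female") else NA_real_,
      diabetes_n = sum(d$diabetes == 1),
      diabetes_pct = if (n > 0) 100 * mean(d$diabetes == 1) else NA_real_,
      smoker_n = sum(d$smoker_current == 1),
      smoker_pct = if (n > 0) 100 * mean(d$smoker_current == 1) else NA_real_,
      age_median = a[1], age_q25 = a[2], age_q75 = a[3],
      sbp_treated_median = st[1], sbp_treated_q25 = st[2],
      sbp_treated_q75 = st[3],
      sbp_untreated_median = su[1], sbp_untreated_q25 = su[2],
      sbp_untreated_q75 = su[3],
      tc_median = tc[1], tc_q25 = tc[2], tc_q75 = tc[3],
      hdl_median = hd[1], hdl_q25 = hd[2], hdl_q75 = hd[3],
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Full between-model comparison report
#'
#' Bundles the comparison statistics computed on one scored cohort: the
#' Spearman concordance matrix, chi-square tests on the category and
#' eligibility tables, per-model eligible proportions with Wilson intervals,
#' discordance, and the high-risk profile table.
#'
#' @param records Analytic sample with [derive_flags()] applied.
#' @param scores data.frame from [score_cohort()].
#' @param scheme Scheme name for categorical comparisons.
#' @return A `cvd_comparison` list.
#' @export
compare_models <- function(records, scores, scheme = "model_specific") {
  categories <- categorize_cohort(scores, schemes = scheme)
  cat_tab <- category_table(categories)
  cat_counts <- stats::xtabs(n ~ model_id + category, data = cat_tab)
  decisions <- statin_decisions(records, scores)
  elig <- eligibility_table(decisions)
  elig_counts <- cbind(eligible = elig$eligible,
                       ineligible = elig$n - elig$eligible)
  rownames(elig_counts) <- elig$model_id
  disc <- find_discordant(categories)
  structure(list(
    scheme = scheme,
    spearman = spearman_matrix(scores),
    category_table = cat_tab,
    category_chisq = chi_square_independence(cat_counts),
    eligibility_table = elig,
    eligibility_chisq = chi_square_independence(elig_counts),
    discordance = disc,
    high_risk_profile = high_risk_profile_summary(records, categories)
  ), class = "cvd_comparison")
}

#' @export
print.cvd_comparison <- function(x, ...) {
  cat("<cvd_comparison> scheme:", x$scheme, "\n")
  rng <- range(x$spearman[upper.tri(x$spearman)])
  cat(sprintf("  Spearman concordance: %.2f to %.2f\n", rng[1], rng[2]))
  cat(sprintf("  category chi-square: %.1f (df %d)\n",
              x$category_chisq$statistic, x$category_chisq$df))
  cat(sprintf("  eligibility chi-square: %.1f (df %d)\n",
              x$eligibility_chisq$statistic, x$eligibility_chisq$df))
  cat("  discordant participants:", x$discordance$n_discordant, "\n")
  invisible(x)
}
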