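# Seeded synthetic cohorts emulating the analytic sample's marginal
# risk-factor distributions via a Gaussian copula: one latent multivariate
# normal draw per participant, pushed through monotone per-variable maps
# (quantile maps for continuous variables, thresholds for binary ones).

.latent_vars <- c("age", "sbp", "dbp", "hdl", "ldl", "vldl", "bmi",
                  "female", "diabetes", "smoker", "treated", "famhx", "hiv")

#' Marginal targets for the synthetic cohort generator
#'
#' Loads the marginal configuration (by default the shipped `haiti_table1`
#' file, which encodes the analytic sample of an urban Haitian cohort of
#' adults >= 40: 60.9% female, age median 54 \[47, 62\], 52.9% hypertension,
#' 18.7% on antihypertensive treatment, 7.8% diabetes, 4.0% current smoking,
#' 21.8% BMI >= 30, 21.0% HDL < 40, 33.5% LDL >= 130, 39.8% SBP >= 140) and
#' assembles the latent correlation matrix.
#'
#' @param config Path to a marginals YAML file; default the shipped
#'   `haiti_table1.yaml`.
#' @param overrides Optional named list merged over the file's values
#'   (e.g. `list(n = 500)`).
#' @return A `cvd_cohort_marginals` list; `$correlation` is the assembled
#'   latent correlation matrix (symmetric positive semi-definite, checked).
#' @export
cohort_marginals <- function(config = NULL, overrides = NULL) {
  if (is.null(config)) {
    config <- system.file("extdata", "haiti_table1.yaml",
                          package = "cvdcompare", mustWork = TRUE)
  }
  m <- yaml::read_yaml(config)
  if (!is.null(overrides)) {
    # the correlation override replaces the pair list wholesale (so an empty
    # list means independence); everything else merges
    lat <- overrides$latent_correlation
    m <- utils::modifyList(m, overrides)
    if (!is.null(lat) || "latent_correlation" %in% names(overrides)) {
      m$latent_correlation <- lat
    }
  }
  stopifnot(m$n > 0, m$prop_female >= 0, m$prop_female <= 1)
  for (p in unlist(m$prevalence)) stopifnot(p >= 0, p <= 1)
  m$correlation <- build_latent_correlation(m$latent_correlation)
  structure(m, class = "cvd_cohort_marginals")
}

build_latent_correlation <- function(pairs) {
  k <- length(.latent_vars)
  sig <- diag(k)
  dimnames(sig) <- list(.latent_vars, .latent_vars)
  for (nm in names(pairs)) {
    vars <- strsplit(nm, "_", fixed = TRUE)[[1]]
    if (length(vars) != 2 || !all(vars %in% .latent_vars)) {
      stop("latent correlation key '", nm,
           "' is not a pair of latent variables", call. = FALSE)
    }
    sig[vars[1], vars[2]] <- sig[vars[2], vars[1]] <- pairs[[nm]]
  }
  ev <- eigen(sig, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("latent correlation matrix is not positive semi-definite",
         call. = FALSE)
  }
  sig
}

# two-piece lognormal above a hard floor: hits floor+q25/median/q75 exactly
asym_lognormal_map <- function(z, floor, q25, med, q75) {
  z75 <- stats::qnorm(0.75)
  mu <- log(med - floor)
  s_lo <- (mu - log(q25 - floor)) / z75
  s_hi <- (log(q75 - floor) - mu) / z75
  floor + exp(mu + z * ifelse(z < 0, s_lo, s_hi))
}

#' Generate a seeded synthetic cohort
#'
#' Deterministic given the seed. Each participant is one row of a latent
#' multivariate normal with the marginals' correlation matrix; continuous
#' variables are monotone maps of their latent coordinate (a two-piece
#' lognormal above 40 for age, normal SBP/DBP, lognormal lipids and BMI) and
#' binary variables are thresholded at their target prevalence. Three SBP
#' readings are emitted by adding independent zero-mean measurement noise to
#' the participant-level true SBP; the true-SBP scale is deflated so the
#' *averaged* SBP (mean of readings 2 and 3) hits the marginal target. Total
#' cholesterol is LDL + HDL + a lognormal VLDL remnant. Prior MI/stroke,
#' statin use and under-40 ages are absent by default (the generator emulates
#' the analytic sample) but can be injected via `prevalence_injected` to
#' exercise the exclusion cascade.
#'
#' @param marginals A [cohort_marginals()] object.
#' @param n Number of participants; defaults to `marginals$n`.
#' @param seed Integer seed; every stochastic draw derives from it.
#' @return data.frame in the cohort CSV schema of [read_cohort()].
#' @export
generate_cohort <- function(marginals = cohort_marginals(),
                            n = marginals$n, seed) {
  stopifnot(inherits(marginals, "cvd_cohort_marginals"), n > 0)
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  set.seed(seed)
  sig <- marginals$correlation
  k <- ncol(sig)
  z <- matrix(stats::rnorm(n * k), n, k) %*% chol(sig)
  colnames(z) <- colnames(sig)
  prev <- marginals$prevalence
  cont <- marginals$continuous
  # upper-tail indicator: positive latent correlation means positive
  # association with the (increasing) continuous maps and other indicators
  thr <- function(var, p) as.integer(z[, var] > stats::qnorm(1 - p))

  age <- asym_lognormal_map(z[, "age"], marginals$age$min, marginals$age$q25,
                            marginals$age$median, marginals$age$q75)
  read_sd <- cont$sbp_reading_sd
  sd_true <- sqrt(cont$sbp$sd^2 - read_sd^2 / 2)
  sbp_true <- cont$sbp$mean + sd_true * z[, "sbp"]
  sbp_true <- pmax(sbp_true, 75)
  readings <- replicate(3, sbp_true + stats::rnorm(n, 0, read_sd))
  dbp <- pmax(cont$dbp$mean + cont$dbp$sd * z[, "dbp"], 40)
  hdl <- exp(log(cont$hdl$median) + cont$hdl$sigma_log * z[, "hdl"])
  ldl <- exp(log(cont$ldl$median) + cont$ldl$sigma_log * z[, "ldl"])
  vldl <- exp(log(cont$vldl$median) + cont$vldl$sigma_log * z[, "vldl"])
  bmi <- exp(log(cont$bmi$median) + cont$bmi$sigma_log * z[, "bmi"])

  inj <- marginals$prevalence_injected
  prior_mi <- stats::rbinom(n, 1, inj$prior_mi)
  prior_stroke <- stats::rbinom(n, 1, inj$prior_stroke)
  on_statin <- stats::rbinom(n, 1, inj$on_statin)
  if (inj$age_lt_40 > 0) {
    young <- stats::rbinom(n, 1, inj$age_lt_40) == 1
    age[young] <- stats::runif(sum(young), 25, 39.9)
  }

  data.frame(
    participant_id = sprintf("P%05d", seq_len(n)),
    age_years = round(age, 1),
    sex = ifelse(thr("female", marginals$prop_female) == 1, "female", "male"),
    tc_mgdl = round(ldl + hdl + vldl, 1),
    hdl_mgdl = round(hdl, 1),
    ldl_mgdl = round(ldl, 1),
    sbp1_mmhg = round(readings[, 1], 1),
    sbp2_mmhg = round(readings[, 2], 1),
    sbp3_mmhg = round(readings[, 3], 1),
    dbp_avg_mmhg = round(dbp, 1),
    bp_treated = thr("treated", prev$bp_treated),
    diabetes = thr("diabetes", prev$diabetes),
    smoker_current = thr("smoker", prev$smoker_current),
    bmi_kgm2 = round(bmi, 1),
    prior_mi = prior_mi,
    prior_stroke = prior_stroke,
    on_statin = on_statin,
    fam_hx_premature_chd = thr("famhx",
                               marginals$prevalence_extra$fam_hx_premature_chd),
    hiv = thr("hiv", marginals$prevalence_extra$hiv),
    stringsAsFactors = FALSE
  )
}

#' Marginal summary of a cohort
#'
#' Reports the same statistics as the cohort's descriptive table: n (%) for
#' binary risk-factor cut-points and median \[IQR\] for age, on the averaged
#' blood pressures.
#'
#' @param records Cohort data.frame (cohort CSV schema).
#' @return data.frame `statistic`, `value` (proportions as fractions, ages in
#'   years).
#' @export
marginal_report <- function(records) {
  stopifnot(nrow(records) > 0)
  if (is.null(records$sbp_avg_mmhg)) {
    records$sbp_avg_mmhg <- average_bp(records$sbp1_mmhg, records$sbp2_mmhg,
                                       records$sbp3_mmhg)
  }
  records <- derive_flags(records)
  q <- stats::quantile(records$age_years, c(0.25, 0.5, 0.75), type = 7,
                       names = FALSE)
  stat <- function(name, value) data.frame(statistic = name, value = value)
  out <- rbind(
    stat("n", nrow(records)),
    stat("prop_female", mean(records$sex == "female")),
    stat("age_q25", q[1]), stat("age_median", q[2]), stat("age_q75", q[3]),
    stat("hypertension", mean(records$hypertension == 1)),
    stat("bp_treated", mean(records$bp_treated == 1)),
    stat("diabetes", mean(records$diabetes == 1)),
    stat("smoker_current", mean(records$smoker_current == 1)),
    stat("bmi_ge_30", mean(records$bmi_kgm2 >= 30)),
    stat("hdl_lt_40", mean(records$hdl_mgdl < 40)),
    stat("ldl_ge_130", mean(records$ldl_mgdl >= 130)),
    stat("sbp_ge_140", mean(records$sbp_avg_mmhg >= 140)),
    stat("dbp_ge_90", mean(!is.na(records$dbp_avg_mmhg) &
                             records$dbp_avg_mmhg >= 90))
  )
  rownames(out) <- NULL
  out
}
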