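# Risk engine: evaluates any declarative model stratum on participant data.

apply_transform <- function(x, transform) {
  switch(transform,
    identity = x,
    log = log(x),
    logsq = log(x)^2,
    squared = x^2,
    stop("unknown transform: ", transform, call. = FALSE)
  )
}

# Covariate values in the stratum's declared units, vectorized over rows.
# `sbp_treated`/`sbp_untreated` carry indicator semantics and are resolved in
# eval_factor so the treatment mask multiplies the *transformed* SBP.
covariate_value <- function(var, data, stratum, ancestry) {
  unit_of <- function(u) if (is.null(stratum$units[[u]])) "mg/dL" else stratum$units[[u]]
  switch(var,
    age = data$age_years,
    total_cholesterol = convert_units(data$tc_mgdl, "mg/dL",
                                      unit_of("total_cholesterol")),
    hdl = convert_units(data$hdl_mgdl, "mg/dL", unit_of("hdl")),
    ldl = convert_units(data$ldl_mgdl, "mg/dL", unit_of("ldl")),
    sbp = data$sbp_avg_mmhg,
    bp_treated = as.numeric(data$bp_treated),
    smoker = as.numeric(data$smoker_current),
    diabetes = as.numeric(data$diabetes),
    bmi = data$bmi_kgm2,
    black = rep(as.numeric(ancestry == "black"), nrow(data)),
    tc_hdl_ratio = data$tc_mgdl / data$hdl_mgdl,
    one = rep(1, nrow(data)),
    stop("unknown covariate: ", var, call. = FALSE)
  )
}

eval_factor <- function(fc, data, stratum, ancestry) {
  if (fc$var %in% c("sbp_treated", "sbp_untreated")) {
    sbp <- data$sbp_avg_mmhg
    if (anyNA(sbp)) stop("missing covariate 'sbp' for model ",
                         stratum$model, call. = FALSE)
    mask <- if (fc$var == "sbp_treated") data$bp_treated == 1 else data$bp_treated == 0
    tr <- apply_transform(sbp, fc$transform)
    return(tr * as.numeric(mask))
  }
  v <- covariate_value(fc$var, data, stratum, ancestry)
  if (anyNA(v)) {
    stop("missing covariate '", fc$var, "' for model ", stratum$model,
         call. = FALSE)
  }
  if (fc$transform %in% c("log", "logsq") && any(v <= 0)) {
    stop("non-positive value passed to log transform of '", fc$var,
         "' in model ", stratum$model, call. = FALSE)
  }
  apply_transform(v, fc$transform)
}

#' Linear predictor of a model stratum
#'
#' Evaluates LP = sum over terms of coefficient x product of (transformed)
#' factors, on the stratum's declared unit system (lipids supplied in mg/dL
#' are converted at evaluation time when the stratum declares mmol/L).
#'
#' @param stratum A validated stratum spec (see [load_model_spec()]).
#' @param data data.frame of participant rows in the cohort schema, with
#'   `sbp_avg_mmhg` present.
#' @param ancestry `"black"` or `"white"`: value of the `black` covariate for
#'   models that carry it as a term rather than a stratum.
#' @return Numeric vector of linear predictors, one per row; deterministic.
#' @export
linear_predictor <- function(stratum, data, ancestry = "black") {
  data <- as.data.frame(data)
  lp <- numeric(nrow(data))
  for (tm in stratum$terms) {
    prod <- rep(1, nrow(data))
    for (fc in tm$factors) prod <- prod * eval_factor(fc, data, stratum, ancestry)
    lp <- lp + as.numeric(tm$coef) * prod
  }
  lp
}

#' Cox baseline-survival risk transform
#'
#' `p = 1 - S0 ^ exp(LP - center)`: 10-year event probability from a linear
#' predictor, the baseline 10-year survival at the centering profile, and the
#' centering constant (the mean linear predictor of the derivation cohort).
#'
#' @param lp Numeric vector of linear predictors.
#' @param s0 Baseline 10-year survival, strictly inside (0, 1).
#' @param center Centering constant subtracted from `lp`.
#' @return Risk probabilities in (0, 1).
#' @examples
#' cox_risk(0, s0 = 0.95, center = 0) # 0.05
#' @export
cox_risk <- function(lp, s0, center) {
  if (!is.finite(s0) || s0 <= 0 || s0 >= 1) {
    stop("baseline survival s0 must lie strictly inside (0, 1)", call. = FALSE)
  }
  1 - s0^exp(lp - center)
}

#' Logistic risk transform
#'
#' `p = 1 / (1 + exp(-LP))`, the inverse-logit used by logistic-form risk
#' equations.
#'
#' @param lp Numeric vector of finite linear predictors.
#' @return Risk probabilities in (0, 1).
#' @examples
#' logistic_risk(0) # 0.5
#' @export
logistic_risk <- function(lp) {
  stats::plogis(lp)
}

#' Score a cohort with one or more risk models
#'
#' Evaluates every requested model on every participant, selecting each
#' participant's coefficient stratum by sex (and by the run-level ancestry
#' setting where the model is ancestry-stratified). Ages outside a model's
#' valid range are scored anyway and flagged, never clamped.
#'
#' @param records Analytic-sample data.frame (see [apply_inclusion_filters()]);
#'   must contain `sbp_avg_mmhg`.
#' @param models Character vector of model ids; default all models in the
#'   registry, in registry order.
#' @param registry Registry directory; defaults to the shipped registry.
#' @param ancestry `"black"` (default) or `"white"`: which ancestry stratum /
#'   indicator value to use for every participant. The default reflects the
#'   target population; it is a required, logged configuration choice.
#' @return data.frame `participant_id`, `model_id`, `lp`, `risk10y`,
#'   `warnings` (empty string or `"age_out_of_range"`), ordered by model then
#'   input row order.
#' @export
score_cohort <- function(records, models = NULL,
                         registry = default_registry(), ancestry = "black") {
  stopifnot(ancestry %in% c("black", "white"))
  if (is.null(models)) models <- list_models(registry)$model_id
  records <- as.data.frame(records)
  if (is.null(records$sbp_avg_mmhg)) {
    records$sbp_avg_mmhg <- average_bp(records$sbp1_mmhg, records$sbp2_mmhg,
                                       records$sbp3_mmhg)
  }
  message("score_cohort: ancestry stratum set to '", ancestry, "' for ",
          nrow(records), " participants")
  out <- vector("list", length(models))
  for (i in seq_along(models)) {
    spec <- load_model_spec(registry, models[i])
    lp <- rep(NA_real_, nrow(records))
    warn <- character(nrow(records))
    for (sex in unique(records$sex)) {
      idx <- which(records$sex == sex)
      stratum <- select_stratum(spec, sex, ancestry)
      lp[idx] <- linear_predictor(stratum, records[idx, , drop = FALSE],
                                  ancestry)
      oor <- records$age_years[idx] < stratum$age_range[1] |
        records$age_years[idx] > stratum$age_range[2]
      warn[idx][oor] <- "age_out_of_range"
      if (stratum$form == "cox") {
        lp[idx] <- lp[idx] # LP kept raw; risk transform below needs stratum
      }
    }
    # risk transform is stratum-specific for cox (s0/center differ by stratum)
    risk <- rep(NA_real_, nrow(records))
    for (sex in unique(records$sex)) {
      idx <- which(records$sex == sex)
      stratum <- select_stratum(spec, sex, ancestry)
      risk[idx] <- if (stratum$form == "cox") {
        cox_risk(lp[idx], stratum$s0, stratum$center)
      } else {
        logistic_risk(lp[idx])
      }
    }
    out[[i]] <- data.frame(
      participant_id = records$participant_id,
      model_id = models[i],
      lp = lp,
      risk10y = risk,
      warnings = warn,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
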