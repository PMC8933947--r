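# Declarative model registry: risk equations are data (YAML configs), not code.

#' Closed vocabularies for model configuration files
#'
#' Covariate names and transforms a model term may reference. `sbp_treated`
#' and `sbp_untreated` are the mutually exclusive treated/untreated systolic
#' blood pressure covariates: they evaluate to the (transformed) SBP multiplied
#' by the treatment (resp. no-treatment) indicator. `one` is the constant 1 and
#' carries logistic intercepts. `black` is the run-level ancestry-stratum
#' indicator.
#'
#' @format Character vectors.
#' @name vocabularies
#' @keywords internal
NULL

.cvd_covariates <- c(
  "age", "total_cholesterol", "hdl", "ldl", "sbp", "sbp_treated",
  "sbp_untreated", "bp_treated", "smoker", "diabetes", "bmi", "black",
  "tc_hdl_ratio", "one"
)
.cvd_transforms <- c("identity", "log", "logsq", "squared")
.cvd_model_ids <- c(
  "pce", "apce", "framingham_lipids", "framingham_bmi", "who_lipids", "who_bmi"
)

#' Path to the coefficient registry shipped with the package
#'
#' @return Directory containing one YAML file per model stratum plus
#'   `index.yaml`.
#' @export
default_registry <- function() {
  system.file("extdata", "models", package = "cvdcompare", mustWork = TRUE)
}

#' Convert lipid concentrations between mg/dL and mmol/L
#'
#' Cholesterol conversion uses the standard factor 38.67 (mg/dL per mmol/L).
#'
#' @param value Numeric vector of concentrations.
#' @param from,to Units, each one of `"mg/dL"` or `"mmol/L"`.
#' @return Converted numeric vector; round-trips recover the input to
#'   within 1e-9 relative.
#' @examples
#' convert_units(38.67, "mg/dL", "mmol/L") # 1
#' @export
convert_units <- function(value, from, to) {
  units <- c("mg/dL", "mmol/L")
  if (!(from %in% units) || !(to %in% units)) {
    stop("unsupported unit pair: ", from, " -> ", to, call. = FALSE)
  }
  if (from == to) return(value)
  if (from == "mg/dL") value / 38.67 else value * 38.67
}

coef_checksum <- function(stratum) {
  coefs <- vapply(stratum$terms, function(t) as.numeric(t$coef), numeric(1))
  sprintf("n:%d;sum:%.6f", length(coefs), sum(coefs))
}

validate_stratum <- function(s, file = "<stratum>") {
  fail <- function(field, msg) {
    stop(sprintf("invalid model spec [%s], field '%s': %s", file, field, msg),
         call. = FALSE)
  }
  for (f in c("model", "stratum", "form", "units", "age_range", "terms")) {
    if (is.null(s[[f]])) fail(f, "missing")
  }
  if (!s$form %in% c("cox", "logistic")) fail("form", "must be cox or logistic")
  if (length(s$terms) == 0) fail("terms", "term list must be non-empty")
  for (tm in s$terms) {
    if (is.null(tm$coef) || !is.finite(as.numeric(tm$coef))) {
      fail("terms", "coefficient missing or non-finite")
    }
    if (is.null(tm$factors) || length(tm$factors) == 0) {
      fail("terms", "each term needs at least one factor")
    }
    for (fc in tm$factors) {
      if (!fc$var %in% .cvd_covariates) {
        fail("terms", paste0("unknown covariate '", fc$var, "'"))
      }
      if (!fc$transform %in% .cvd_transforms) {
        fail("terms", paste0("unknown transform '", fc$transform, "'"))
      }
    }
  }
  if (s$form == "cox") {
    if (is.null(s$s0)) fail("s0", "cox form requires baseline survival")
    if (!is.finite(s$s0) || s$s0 <= 0 || s$s0 >= 1) {
      fail("s0", "baseline survival must lie strictly inside (0, 1)")
    }
    if (is.null(s$center) || !is.finite(as.numeric(s$center))) {
      fail("center", "cox form requires a finite centering constant")
    }
  } else {
    has_int <- any(vapply(s$terms, function(t) {
      length(t$factors) == 1 && t$factors[[1]]$var == "one"
    }, logical(1)))
    if (!has_int) fail("terms", "logistic form requires an intercept term (var 'one')")
  }
  for (u in names(s$units)) {
    ok <- switch(u,
      total_cholesterol = , hdl = , ldl = s$units[[u]] %in% c("mg/dL", "mmol/L"),
      sbp = s$units[[u]] == "mmHg",
      bmi = s$units[[u]] == "kg/m2",
      FALSE
    )
    if (!ok) fail("units", paste0("inconsistent unit for '", u, "'"))
  }
  if (length(s$age_range) != 2 || s$age_range[1] >= s$age_range[2]) {
    fail("age_range", "must be c(min, max) with min < max")
  }
  if (!is.null(s$checksum) && !identical(s$checksum, "TBD")) {
    if (!identical(s$checksum, coef_checksum(s))) {
      fail("checksum", sprintf("transcription checksum mismatch (expected %s, file says %s)",
                               coef_checksum(s), s$checksum))
    }
  }
  invisible(s)
}

read_stratum_file <- function(path) {
  if (!file.exists(path)) stop("model spec file not found: ", path, call. = FALSE)
  s <- yaml::read_yaml(path)
  s$age_range <- as.numeric(unlist(s$age_range))
  validate_stratum(s, file = basename(path))
  s
}

read_index <- function(registry) {
  idx_path <- file.path(registry, "index.yaml")
  if (!dir.exists(registry) || !file.exists(idx_path)) {
    stop("registry directory unreadable or missing index.yaml: ", registry,
         call. = FALSE)
  }
  yaml::read_yaml(idx_path)$models
}

#' Load and validate the specification of one risk model
#'
#' Reads every stratum file of the model from a registry directory, validates
#' each against the config schema (closed covariate/transform vocabularies,
#' baseline survival in (0,1) and a centering constant for Cox-form models, an
#' intercept term for logistic-form models, consistent units, transcription
#' checksum), and returns the assembled model.
#'
#' @param path Registry directory (containing `index.yaml`), e.g.
#'   [default_registry()].
#' @param model_id One of `"pce"`, `"apce"`, `"framingham_lipids"`,
#'   `"framingham_bmi"`, `"who_lipids"`, `"who_bmi"` (for the shipped
#'   registry).
#' @return A `cvd_model_spec`: list with `model_id`, `form`, `label`, and
#'   `strata` (a list of validated stratum specs, each carrying `stratum`
#'   keys, `terms`, units, age range, and for Cox models `s0` and `center`).
#' @export
load_model_spec <- function(path, model_id) {
  idx <- read_index(path)
  ids <- vapply(idx, function(m) m$id, character(1))
  if (!model_id %in% ids) {
    stop("unknown model id '", model_id, "' (registry has: ",
         paste(ids, collapse = ", "), ")", call. = FALSE)
  }
  entry <- idx[[match(model_id, ids)]]
  strata <- lapply(entry$strata, function(st) {
    s <- read_stratum_file(file.path(path, st$file))
    if (!identical(s$model, model_id)) {
      stop("stratum file ", st$file, " declares model '", s$model,
           "' but index lists it under '", model_id, "'", call. = FALSE)
    }
    s
  })
  spec <- structure(
    list(model_id = model_id, form = entry$form, label = entry$label,
         strata = strata),
    class = "cvd_model_spec"
  )
  forms <- unique(vapply(strata, function(s) s$form, character(1)))
  if (!identical(forms, spec$form)) {
    stop("stratum files of '", model_id, "' disagree with index on form",
         call. = FALSE)
  }
  spec
}

#' @export
print.cvd_model_spec <- function(x, ...) {
  cat("<cvd_model_spec> ", x$model_id, " (", x$form, " form), ",
      length(x$strata), " strata\n", sep = "")
  for (s in x$strata) {
    key <- paste(unlist(s$stratum), collapse = "/")
    cat("  ", key, ": ", length(s$terms), " terms",
        if (s$form == "cox") sprintf(", S0 = %.5f", s$s0) else "", "\n",
        sep = "")
  }
  invisible(x)
}

#' List the models available in a registry
#'
#' @param registry Registry directory; defaults to the shipped registry.
#' @return data.frame with one row per model, in the index's stable order:
#'   `model_id`, `form`, `n_strata`, `label`.
#' @export
list_models <- function(registry = default_registry()) {
  idx <- read_index(registry)
  data.frame(
    model_id = vapply(idx, function(m) m$id, character(1)),
    form = vapply(idx, function(m) m$form, character(1)),
    n_strata = vapply(idx, function(m) length(m$strata), integer(1)),
    label = vapply(idx, function(m) m$label, character(1)),
    stringsAsFactors = FALSE
  )
}

#' Select the coefficient stratum of a model for one participant
#'
#' @param spec A `cvd_model_spec`.
#' @param sex `"female"` or `"male"`.
#' @param ancestry `"black"` or `"white"`; only consulted when the model is
#'   ancestry-stratified.
#' @return A validated stratum spec.
#' @keywords internal
select_stratum <- function(spec, sex, ancestry = "black") {
  for (s in spec$strata) {
    if (!identical(s$stratum$sex, sex)) next
    if (!is.null(s$stratum$ancestry) && !identical(s$stratum$ancestry, ancestry)) next
    return(s)
  }
  stop("no stratum of '", spec$model_id, "' for sex=", sex,
       ", ancestry=", ancestry, call. = FALSE)
}
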