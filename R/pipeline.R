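# End-to-end orchestration: simulate or ingest -> prep -> score ->
# categorize -> statin -> compare, with a reproducible run manifest.

#' Configuration for an end-to-end pipeline run
#'
#' @param input Path to a cohort CSV, or `NULL` to simulate.
#' @param simulate_n Cohort size when simulating (ignored with `input`).
#' @param seed Integer seed used for simulation.
#' @param models Model ids to score; default all six.
#' @param schemes Threshold scheme names to categorize under.
#' @param ancestry Ancestry stratum setting passed to [score_cohort()].
#' @param out_dir Output directory (created if needed).
#' @return A `cvd_run_config` list.
#' @export
run_config <- function(input = NULL, simulate_n = 1000, seed = 1,
                       models = NULL,
                       schemes = c("uniform", "model_specific"),
                       ancestry = "black", out_dir = tempfile("cvdrun")) {
  if (is.null(models)) models <- .cvd_model_ids
  stopifnot(length(models) >= 1, all(schemes %in% c("uniform", "model_specific")))
  structure(list(input = input, simulate_n = simulate_n, seed = seed,
                 models = models, schemes = schemes, ancestry = ancestry,
                 out_dir = out_dir),
            class = "cvd_run_config")
}

write_stage <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full comparison pipeline
#'
#' Sequences the analysis end to end: cohort acquisition (simulation with the
#' configured seed, or ingestion of a cohort CSV), blood-pressure averaging
#' and the inclusion cascade, derived flags, risk scoring for every selected
#' model, categorization under the selected schemes, statin decisions, and
#' the between-model comparison report. All stage outputs are written to the
#' output directory as delimited text plus a JSON comparison report, and a
#' manifest records the configuration, package version, and an MD5 checksum
#' per output file, so a re-run of the same manifest reproduces the outputs
#' bit for bit.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory stage results and
#'   `manifest_path`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "cvd_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(config$out_dir)) {
    stop("output directory not writable: ", config$out_dir, call. = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  cohort <- stage("cohort", {
    if (is.null(config$input)) {
      generate_cohort(cohort_marginals(), n = config$simulate_n,
                      seed = config$seed)
    } else {
      read_cohort(config$input)$records
    }
  })
  files <- character(0)
  files["cohort"] <- write_stage(cohort, file.path(config$out_dir, "cohort.csv"))
  prep <- stage("prep", {
    cohort$sbp_avg_mmhg <- average_bp(cohort$sbp1_mmhg, cohort$sbp2_mmhg,
                                      cohort$sbp3_mmhg)
    flt <- apply_inclusion_filters(cohort)
    list(sample = suppressWarnings(derive_flags(flt$sample)),
         report = flt$report)
  })
  files["exclusions"] <- write_stage(
    as.data.frame(unclass(prep$report)),
    file.path(config$out_dir, "exclusions.csv")
  )
  scores <- stage("score", suppressMessages(
    score_cohort(prep$sample, config$models, ancestry = config$ancestry)
  ))
  files["scores"] <- write_stage(scores, file.path(config$out_dir, "scores.csv"))
  categories <- stage("categorize",
                      categorize_cohort(scores, schemes = config$schemes))
  files["categories"] <- write_stage(categories,
                                     file.path(config$out_dir, "categories.csv"))
  decisions <- stage("statin", statin_decisions(prep$sample, scores))
  files["statin"] <- write_stage(decisions,
                                 file.path(config$out_dir, "statin.csv"))
  comparisons <- stage("compare", {
    lapply(stats::setNames(config$schemes, config$schemes), function(sn) {
      cmp <- compare_models(prep$sample, scores, scheme = sn)
      list(scheme = sn,
           spearman = cmp$spearman,
           category_table = cmp$category_table,
           category_chisq = cmp$category_chisq,
           eligibility_table = cmp$eligibility_table,
           eligibility_chisq = cmp$eligibility_chisq,
           n_discordant = cmp$discordance$n_discordant,
           high_risk_profile = cmp$high_risk_profile)
    })
  })
  files["comparison"] <- file.path(config$out_dir, "comparison.json")
  jsonlite::write_json(comparisons, files["comparison"], digits = NA,
                       auto_unbox = TRUE, dataframe = "columns")
  manifest <- list(
    package = "cvdcompare",
    version = as.character(utils::packageVersion("cvdcompare")),
    config = unclass(config)[setdiff(names(unclass(config)), "out_dir")],
    outputs = lapply(stats::setNames(names(files), names(files)), function(nm) {
      list(file = basename(files[[nm]]),
           md5 = unname(tools::md5sum(files[[nm]])))
    })
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(list(cohort = cohort, prep = prep, scores = scores,
                 categories = categories, decisions = decisions,
                 comparisons = comparisons, files = files,
                 manifest_path = manifest_path))
}
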