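#!/usr/bin/env Rscript
# Thin command-line wrapper over cvdcompare::run_pipeline().
# Exit codes: 0 success, 2 configuration error, 3 stage error.

suppressPackageStartupMessages({
  library(optparse)
  library(cvdcompare)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--input", type = "character", default = NULL,
              help = "cohort CSV; omit to simulate"),
  make_option("--n", type = "integer", default = 1000L,
              help = "simulated cohort size [default %default]"),
  make_option("--seed", type = "integer", default = 1L,
              help = "simulation seed [default %default]"),
  make_option("--models", type = "character", default = "all",
              help = "comma-separated model ids, or 'all'"),
  make_option("--scheme", type = "character", default = "both",
              help = "uniform, model_specific, or both"),
  make_option("--ancestry-stratum", type = "character", default = "black",
              dest = "ancestry", help = "black or white [default %default]"),
  make_option("--out", type = "character", default = "cvd_run",
              help = "output directory [default %default]"),
  make_option("--verbose", action = "store_true", default = FALSE)
)))

fail <- function(code, msg) {
  message("ERROR: ", msg)
  quit(status = code, save = "no")
}

models <- if (identical(opts$models, "all")) NULL else
  strsplit(opts$models, ",", fixed = TRUE)[[1]]
schemes <- switch(opts$scheme,
  both = c("uniform", "model_specific"),
  uniform = "uniform",
  model_specific = "model_specific",
  fail(2, "unknown --scheme (use uniform, model_specific, or both)")
)
if (!opts$ancestry %in% c("black", "white")) {
  fail(2, "--ancestry-stratum must be black or white")
}
if (!is.null(opts$input) && !file.exists(opts$input)) {
  fail(2, paste("input file not found:", opts$input))
}

cfg <- tryCatch(
  run_config(input = opts$input, simulate_n = opts$n, seed = opts$seed,
             models = models, schemes = schemes, ancestry = opts$ancestry,
             out_dir = opts$out),
  error = function(e) fail(2, conditionMessage(e))
)
res <- tryCatch(
  if (opts$verbose) run_pipeline(cfg) else
    suppressWarnings(suppressMessages(run_pipeline(cfg))),
  error = function(e) fail(3, conditionMessage(e))
)
message("INFO: outputs in ", opts$out)
quit(status = 0, save = "no")
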