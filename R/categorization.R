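# Risk categorization under uniform and model-specific threshold schemes,
# and low/high discordance between models.

#' Threshold schemes for risk categorization
#'
#' Two schemes are supported. `uniform` applies low < 5%, intermediate
#' 5 to < 7.5%, high >= 7.5% to every model. `model_specific` applies each
#' model family's native cut-points: PCE and adjusted PCE 5%/7.5%; the two
#' Framingham models 10%/20%; the two WHO models 5%/20%. Intervals are
#' left-closed, right-open, with the top category closed at its cut
#' (a risk exactly at the upper cut is high).
#'
#' @param name `"uniform"` or `"model_specific"`.
#' @return A `cvd_threshold_scheme`: list with `name` and `cuts`, a named list
#'   of `c(c1, c2)` per model id with 0 < c1 < c2 < 1.
#' @export
threshold_scheme <- function(name = c("uniform", "model_specific")) {
  name <- match.arg(name)
  cuts <- if (name == "uniform") {
    stats::setNames(rep(list(c(0.05, 0.075)), length(.cvd_model_ids)),
                    .cvd_model_ids)
  } else {
    list(
      pce = c(0.05, 0.075),
      apce = c(0.05, 0.075),
      framingham_lipids = c(0.10, 0.20),
      framingham_bmi = c(0.10, 0.20),
      who_lipids = c(0.05, 0.20),
      who_bmi = c(0.05, 0.20)
    )
  }
  for (cc in cuts) stopifnot(cc[1] > 0, cc[1] < cc[2], cc[2] < 1)
  structure(list(name = name, cuts = cuts), class = "cvd_threshold_scheme")
}

.cvd_categories <- c("low", "intermediate", "high")

#' Categorize continuous risks
#'
#' low iff risk < c1; intermediate iff c1 <= risk < c2; high iff risk >= c2.
#' Risks are compared at full precision, never rounded first.
#'
#' @param risk Numeric vector of probabilities in \[0, 1\].
#' @param model_id Model id (scalar or vector matching `risk`) used to look up
#'   cut-points under the scheme.
#' @param scheme A [threshold_scheme()].
#' @return Factor with levels low/intermediate/high.
#' @export
categorize <- function(risk, model_id, scheme) {
  stopifnot(inherits(scheme, "cvd_threshold_scheme"),
            all(risk >= 0 & risk <= 1))
  model_id <- rep_len(model_id, length(risk))
  unknown <- setdiff(unique(model_id), names(scheme$cuts))
  if (length(unknown) > 0) {
    stop("no cut-points for model id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  c1 <- vapply(scheme$cuts[model_id], `[`, numeric(1), 1)
  c2 <- vapply(scheme$cuts[model_id], `[`, numeric(1), 2)
  out <- ifelse(risk < c1, "low", ifelse(risk < c2, "intermediate", "high"))
  factor(out, levels = .cvd_categories)
}

#' Categorize a score table under one or both schemes
#'
#' @param scores data.frame from [score_cohort()].
#' @param schemes Character vector among `"uniform"`, `"model_specific"`.
#' @return Tidy data.frame `participant_id`, `model_id`, `scheme`, `category`.
#' @export
categorize_cohort <- function(scores,
                              schemes = c("uniform", "model_specific")) {
  out <- lapply(schemes, function(sn) {
    sch <- threshold_scheme(sn)
    data.frame(
      participant_id = scores$participant_id,
      model_id = scores$model_id,
      scheme = sn,
      category = categorize(scores$risk10y, scores$model_id, sch),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-model category counts and proportions
#'
#' @param categories Tidy category data.frame ([categorize_cohort()]),
#'   already restricted to one scheme or carrying a `scheme` column to group
#'   by.
#' @return data.frame with one row per (scheme, model, category): `n`, and
#'   `prop` of that model's cohort. Per-model counts sum to the cohort n.
#' @export
category_table <- function(categories) {
  if (is.null(categories$scheme)) categories$scheme <- "unspecified"
  tab <- as.data.frame(table(scheme = categories$scheme,
                             model_id = categories$model_id,
                             category = categories$category))
  names(tab)[names(tab) == "Freq"] <- "n"
  totals <- stats::aggregate(n ~ scheme + model_id, data = tab, FUN = sum)
  names(totals)[3] <- "n_total"
  tab <- merge(tab, totals, by = c("scheme", "model_id"), sort = FALSE)
  tab$prop <- ifelse(tab$n_total > 0, tab$n / tab$n_total, NA_real_)
  tab[order(tab$scheme, tab$model_id, tab$category),
      c("scheme", "model_id", "category", "n", "prop")]
}

#' Find participants with discordant risk categories
#'
#' A participant is discordant iff some model calls them low risk while
#' another calls them high risk (intermediate never triggers discordance).
#' The pattern tabulation records, per discordant participant, which models
#' called high and which called low.
#'
#' @param categories Tidy category data.frame for a single scheme.
#' @return List with `discordant_ids`, `n_discordant`, and `patterns`
#'   (data.frame `participant_id`, `models_high`, `models_low`, the model-id
#'   lists comma-joined in registry order).
#' @export
find_discordant <- function(categories) {
  if (length(unique(categories$scheme)) > 1) {
    stop("find_discordant() expects categories from a single scheme",
         call. = FALSE)
  }
  split_by_p <- split(categories, categories$participant_id)
  rows <- lapply(split_by_p, function(d) {
    lows <- d$model_id[d$category == "low"]
    highs <- d$model_id[d$category == "high"]
    if (length(lows) > 0 && length(highs) > 0) {
      data.frame(
        participant_id = d$participant_id[1],
        models_high = paste(sort_models(highs), collapse = ","),
        models_low = paste(sort_models(lows), collapse = ","),
        stringsAsFactors = FALSE
      )
    }
  })
  patterns <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(patterns)) {
    patterns <- data.frame(participant_id = character(0),
                           models_high = character(0),
                           models_low = character(0))
  }
  rownames(patterns) <- NULL
  list(discordant_ids = patterns$participant_id,
       n_discordant = nrow(patterns),
       patterns = patterns)
}

# canonical registry order, unknown ids last alphabetically
sort_models <- function(ids) {
  ids[order(match(ids, .cvd_model_ids), ids)]
}
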