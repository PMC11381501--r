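#' @title Reporting pipeline
#' @description
#' Ties the stages into a reproducible run: scoring, disability
#' classification with PTA concordance, the validation battery
#' (descriptives, floor/ceiling, the six published reliability
#' combinations) and the exploratory factor analysis.  Every run writes a
#' manifest with input digests, the seed and the package version;
#' identical inputs and seed reproduce identical outputs.
#' @name io_cli
NULL

# Item selections of the six published reliability combinations.
# The source tabulates combinations 3 and 4 as 36/42 items while the
# score-group definition gives 37/41; the bank's 37/41 split is canonical
# here (the published raw maxima 148 = 37*4 and 164 = 41*4 confirm it).
alpha_combinations <- function(bank) {
  num <- item_number(bank$items$id)
  list(
    bf_excl_voice_speech = bank$items$id[num %in% setdiff(1:48, 41:48)],
    activities_participation = bank$items$id[num %in% 49:74],
    hearing_related = items_in_group(bank, "hearing_related"),
    non_hearing_related = items_in_group(bank, "non_hearing_related"),
    all_scored = items_in_group(bank, "all_scored"),
    all_excl_voice_speech_aided = bank$items$id[num %in% setdiff(1:90, 41:48)])
}

#' Reliability table over the six published item combinations
#'
#' Combinations: body functions excluding the voice/speech block (40
#' items), activities and participation (26), hearing-related (37),
#' non-hearing-related (41), both score groups (78), and all items except
#' the voice/speech block (82, computed on hearing-aid users only so the
#' aid-benefit items are graded).  A combination with fewer than two
#' complete respondents is reported as `NA` with a note.
#'
#' @param cohort an `hc_cohort`.
#' @param bank item bank.
#' @return Data frame: `combination`, `n_items`, `n_complete`, `alpha`,
#'   `note`.
#' @export
alpha_table <- function(cohort, bank) {
  combos <- alpha_combinations(bank)
  out <- data.frame(combination = names(combos),
                    n_items = lengths(combos),
                    n_complete = NA_integer_, alpha = NA_real_,
                    note = "", stringsAsFactors = FALSE, row.names = NULL)
  for (i in seq_along(combos)) {
    sub <- cohort
    if (names(combos)[i] == "all_excl_voice_speech_aided") {
      keep <- isTRUE_vec(cohort$demo$hearing_aid_user)
      sub <- structure(list(demo = cohort$demo[keep, , drop = FALSE],
                            responses = cohort$responses[keep, , drop = FALSE],
                            bank_version = cohort$bank_version),
                       class = "hc_cohort")
      out$note[i] <- "aided respondents only"
    }
    res <- tryCatch(cronbach_alpha(sub, items = combos[[i]], bank = bank),
                    error = function(e) e)
    if (inherits(res, "error")) {
      out$note[i] <- paste0(out$note[i],
                            if (nzchar(out$note[i])) "; " else "",
                            "insufficient data: ", conditionMessage(res))
    } else {
      out$n_complete[i] <- res$n_complete_respondents
      out$alpha[i] <- res$alpha
    }
  }
  out
}

#' Run the analysis pipeline
#'
#' @param cohort an `hc_cohort` or a path to a cohort CSV.
#' @param steps ordered subset of `c("score", "classify", "validate",
#'   "efa")`; `"classify"` requires `"score"` earlier in the list.
#' @param out_dir output directory (created if needed).
#' @param bank item bank.
#' @param policy scoring policy.
#' @param thresholds `"published"` for the published disability cut points or
#'   `"derive"` for cohort-derived ones.
#' @param seed integer recorded in the manifest and used for any
#'   stochastic step.
#' @return Invisibly, a list with the in-memory results (`scores`,
#'   `degrees`, `concordance`, `descriptives`, `alpha_table`, `efa`,
#'   `manifest`) with per-step files written under `out_dir`.
#' @export
run_pipeline <- function(cohort, steps = c("score", "classify", "validate",
                                           "efa"),
                         out_dir, bank = load_item_bank(),
                         policy = score_policy(),
                         thresholds = c("published", "derive"), seed = 1L) {
  thresholds <- match.arg(thresholds)
  steps <- match.arg(steps, c("score", "classify", "validate", "efa"),
                     several.ok = TRUE)
  if (!length(steps)) stop("no step requested")
  if ("classify" %in% steps &&
      (!"score" %in% steps ||
       match("score", steps) > match("classify", steps))) {
    stop("step dependency violation: 'classify' requires 'score' before it")
  }
  input_digest <- NA_character_
  if (is.character(cohort)) {
    input_digest <- unname(tools::md5sum(cohort))
    cohort <- read_cohort(cohort, bank)
  }
  stopifnot(inherits(cohort, "hc_cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  res <- list()
  summary <- list(n_respondents = nrow(cohort$demo))

  for (step in steps) {
    if (step == "score") {
      res$scores <- score_cohort(cohort, bank, policy)
      utils::write.csv(res$scores, file.path(out_dir, "scores.csv"),
                       row.names = FALSE, na = "")
      summary$score_means <- lapply(
        c("norm_hearing", "norm_non_hearing", "norm_speech"),
        function(cn) mean(res$scores[[cn]], na.rm = TRUE))
      names(summary$score_means) <- c("hearing", "non_hearing", "speech")
    } else if (step == "classify") {
      thr <- list(
        hearing_related = if (thresholds == "published")
          published_thresholds("hearing_related")
        else derive_thresholds(res$scores$norm_hearing, "hearing_related"),
        non_hearing_related = if (thresholds == "published")
          published_thresholds("non_hearing_related")
        else derive_thresholds(res$scores$norm_non_hearing,
                               "non_hearing_related"),
        speech_perception = if (thresholds == "published")
          published_thresholds("speech_perception")
        else derive_thresholds(res$scores$norm_speech, "speech_perception"))
      deg <- data.frame(
        id = res$scores$id,
        degree_hearing = classify_disability(res$scores$norm_hearing,
                                             thr$hearing_related),
        degree_non_hearing = classify_disability(
          res$scores$norm_non_hearing, thr$non_hearing_related),
        degree_speech = classify_disability(res$scores$norm_speech,
                                            thr$speech_perception))
      if (any(is.finite(cohort$demo$pta_better))) {
        deg$hearing_category <- classify_hearing(
          ifelse(is.finite(cohort$demo$pta_better),
                 cohort$demo$pta_better, 0))
        deg$hearing_category[!is.finite(cohort$demo$pta_better)] <- NA
        conc <- concordance_table(cohort, res$scores, thr$hearing_related)
        res$concordance <- conc
        utils::write.csv(as.data.frame(conc$table),
                         file.path(out_dir, "concordance.csv"),
                         row.names = FALSE)
        summary$concordance_ratios <- as.list(conc$marginal_ratios)
      }
      res$degrees <- deg
      utils::write.csv(deg, file.path(out_dir, "degrees.csv"),
                       row.names = FALSE, na = "")
    } else if (step == "validate") {
      res$descriptives <- describe_items(cohort, bank)
      utils::write.csv(res$descriptives,
                       file.path(out_dir, "descriptives.csv"),
                       row.names = FALSE, na = "")
      res$alpha_table <- alpha_table(cohort, bank)
      utils::write.csv(res$alpha_table,
                       file.path(out_dir, "alpha_table.csv"),
                       row.names = FALSE, na = "")
      summary$alpha <- stats::setNames(as.list(res$alpha_table$alpha),
                                       res$alpha_table$combination)
    } else if (step == "efa") {
      g <- coded_grades(cohort, bank)[, items_in_group(bank, "all_scored"),
                                      drop = FALSE]
      res$efa <- paf_promax(g)
      utils::write.csv(
        data.frame(item_id = rownames(res$efa$loadings),
                   round(res$efa$loadings, 4),
                   communality = round(res$efa$communalities, 4)),
        file.path(out_dir, "efa_loadings.csv"), row.names = FALSE)
      summary$efa <- list(n_factors = res$efa$n_factors,
                          kmo = res$efa$kmo,
                          bartlett_chi2 = res$efa$bartlett_chi2,
                          bartlett_df = res$efa$bartlett_df,
                          variance_explained = res$efa$variance_explained)
    }
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  manifest <- list(
    command = paste(steps, collapse = "+"),
    seed = seed,
    input_digest = input_digest,
    bank_version = bank$version,
    package_version = as.character(utils::packageVersion("hearcommand")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
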