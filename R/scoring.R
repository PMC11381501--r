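#' @title Outcome scores
#' @description
#' Three outcome scores summarize the instrument: hearing-related (37
#' items, labels A, C, E), non-hearing-related (41 items, labels B, D, F,
#' G) and speech perception (the 32 hearing-related items whose target
#' sounds include speech).  Grades of the six environmental-facilitator
#' items `H.75`--`H.80` are mirrored (`4 - grade`) so that 4 always means
#' the highest level of hardship.  Raw group sums (maxima 148, 164 and
#' 128) are normalized to a 0--10 scale.
#' @name scoring
NULL

.hc_published_coef <- c(`37` = 0.067, `41` = 0.061, `32` = 0.0782)
.hc_group_sizes <- c(hearing_related = 37L, non_hearing_related = 41L,
                     speech_perception = 32L)

#' Mirror a facilitator grade
#'
#' For environmental facilitators a profound/complete response (4) eases
#' functioning, so before score aggregation the numeric value is reflected:
#' 4 becomes 0, 3 becomes 1, 2 stays 2, 1 becomes 3, 0 becomes 4.
#'
#' @param grade integer grade(s) in 0..4.
#' @return `4 - grade`.
#' @export
mirror_value <- function(grade) {
  if (any(is.na(grade)) || any(!grade %in% 0:4)) {
    stop("grade must be in 0..4")
  }
  4L - as.integer(grade)
}

#' Coded value of a response for score computation
#'
#' Graded responses pass through [mirror_value()] iff the item's polarity
#' is `MIRRORED`; any non-gradable response codes to `NA`.
#'
#' @param item item id.
#' @param value response token (`"0"`..`"4"`, `"DK"`, `"NA"`, `"NR"`, `""`)
#'   or integer grade.
#' @param bank item bank.
#' @return Integer 0--4, or `NA` for non-gradable responses.
#' @export
coded_value <- function(item, value, bank) {
  stopifnot(inherits(bank, "hc_bank"))
  row <- match(item, bank$items$id)
  if (is.na(row)) stop("unknown item id: ", item)
  v <- as.character(value)
  if (!v %in% as.character(0:4)) return(NA_integer_)
  g <- as.integer(v)
  if (bank$items$polarity[row] == "MIRRORED") mirror_value(g) else g
}

#' Normalization coefficient for a score group
#'
#' In `"exact"` mode the coefficient is `10 / (4 * group_size)`, mapping a
#' maximal raw score exactly to 10.  In `"published"` mode the printed
#' constants are returned: 0.067 (hearing-related, a truncation of
#' 10/148 = 0.06757), 0.061 (non-hearing-related) and 0.0782 (speech
#' perception).
#'
#' @param group_size number of items in the group (must be 37, 41 or 32 in
#'   published mode).
#' @param mode `"published"` or `"exact"`.
#' @return Weight per raw point.
#' @export
normalization_coefficient <- function(group_size,
                                      mode = c("published", "exact")) {
  mode <- match.arg(mode)
  stopifnot(length(group_size) == 1L, is.finite(group_size), group_size > 0)
  if (mode == "exact") return(10 / (4 * group_size))
  key <- as.character(group_size)
  if (!key %in% names(.hc_published_coef)) {
    stop("no published coefficient for group size ", group_size,
         " (known sizes: 37, 41, 32)")
  }
  unname(.hc_published_coef[key])
}

#' Scoring policy
#'
#' @param mode `"published"` (printed coefficients; normalized score
#'   defined only at full coverage), `"exact"` (coefficient `10/(4n)`,
#'   full coverage required), or `"prorated"` (default:
#'   `10 * raw / (4 * n_graded)`, preserving the 0--10 reading under
#'   missing responses).
#' @param min_coverage minimum fraction of a group's items that must be
#'   graded for the score to be valid (default 0.80).
#' @return A `hc_score_policy` list.
#' @export
score_policy <- function(mode = c("prorated", "published", "exact"),
                         min_coverage = 0.80) {
  mode <- match.arg(mode)
  stopifnot(min_coverage >= 0, min_coverage <= 1)
  structure(list(mode = mode, min_coverage = min_coverage),
            class = "hc_score_policy")
}

#' Score one respondent
#'
#' Computes raw and normalized hearing-related, non-hearing-related and
#' speech-perception scores.  Raw scores sum the coded (mirrored where
#' applicable) grades over the graded items of each group.  Normalization
#' depends on the policy mode; coverage (fraction of group items graded)
#' is recorded, and a score is flagged invalid when coverage falls below
#' the policy's `min_coverage` (in `published`/`exact` modes the
#' normalized value additionally requires full coverage).
#'
#' @param respondent a single-respondent `hc_cohort`, or a row index / id
#'   into `cohort`.
#' @param bank item bank.
#' @param policy a [score_policy()].
#' @param cohort optional `hc_cohort` when `respondent` is an index or id.
#' @return A one-row data frame (class `hc_scores`): `id`, `raw_*`,
#'   `norm_*`, `coverage_*`, `valid_*`, `mode`.
#' @export
score_respondent <- function(respondent, bank, policy = score_policy(),
                             cohort = NULL) {
  if (!inherits(respondent, "hc_cohort")) {
    stopifnot(inherits(cohort, "hc_cohort"))
    i <- if (is.character(respondent)) match(respondent, cohort$demo$id)
         else as.integer(respondent)
    if (is.na(i) || i < 1L || i > nrow(cohort$demo)) {
      stop("respondent not found in cohort")
    }
    respondent <- structure(
      list(demo = cohort$demo[i, , drop = FALSE],
           responses = cohort$responses[i, , drop = FALSE],
           bank_version = cohort$bank_version),
      class = "hc_cohort")
  }
  score_cohort(respondent, bank, policy)[1, , drop = FALSE]
}

#' Score a whole cohort
#'
#' @param cohort an `hc_cohort` (gating applied).
#' @param bank item bank.
#' @param policy a [score_policy()].
#' @return Data frame with one row per respondent (class `hc_scores`).
#' @export
score_cohort <- function(cohort, bank, policy = score_policy()) {
  stopifnot(inherits(cohort, "hc_cohort"), inherits(bank, "hc_bank"),
            inherits(policy, "hc_score_policy"))
  coded <- coded_grades(cohort, bank)
  out <- data.frame(id = cohort$demo$id, stringsAsFactors = FALSE)
  for (grp in names(.hc_group_sizes)) {
    ids <- items_in_group(bank, grp)
    n_group <- .hc_group_sizes[[grp]]
    sub <- coded[, ids, drop = FALSE]
    n_graded <- rowSums(!is.na(sub))
    raw <- rowSums(sub, na.rm = TRUE)
    raw[n_graded == 0L] <- NA_real_
    coverage <- n_graded / n_group
    norm <- switch(policy$mode,
      prorated = ifelse(n_graded > 0L, 10 * raw / (4 * n_graded), NA_real_),
      # printed coefficients are rounded (164 * 0.061 = 10.004), so the
      # published-mode scale is capped at 10
      published = ifelse(coverage == 1,
                         pmin(10, raw * normalization_coefficient(n_group,
                                                                  "published")),
                         NA_real_),
      exact = ifelse(coverage == 1,
                     raw * normalization_coefficient(n_group, "exact"),
                     NA_real_))
    valid <- coverage >= policy$min_coverage & !is.na(norm)
    key <- sub("_related|_perception", "", grp)
    key <- c(hearing = "hearing", non_hearing = "non_hearing",
             speech = "speech")[[key]]
    out[[paste0("raw_", key)]] <- raw
    out[[paste0("norm_", key)]] <- norm
    out[[paste0("coverage_", key)]] <- coverage
    out[[paste0("valid_", key)]] <- valid
  }
  out$mode <- policy$mode
  class(out) <- c("hc_scores", "data.frame")
  out
}

# full coded (mirrored) grade matrix for a cohort
coded_grades <- function(cohort, bank) {
  g <- response_grades(cohort)
  mir <- bank$items$id[bank$items$polarity == "MIRRORED"]
  g[, mir] <- 4 - g[, mir]
  g
}
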