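#' @title Hearing-loss and disability classification
#' @description
#' Hearing loss is classified from the better-ear pure-tone average (PTA,
#' mean threshold at 0.5/1/2/4 kHz) following the Global Burden of Disease
#' expert-group bands: normal < 20 dB HL, mild 20--35, moderate 35--50,
#' moderately severe 50--65.  The validation population excluded
#' severe-to-profound loss, so a PTA of 65 dB HL or more is flagged out of
#' the validated range rather than classified.
#'
#' Disability degrees (No/Mild/Moderate/Severe) are assigned from a
#' normalized outcome score using the population mean M and standard
#' deviation SD: No below `M - SD`, Mild in `[M - SD, M)`, Moderate in
#' `[M, M + SD)`, Severe at `M + SD` and above.  The published reference
#' cut points are population-dependent; cohort-specific thresholds can be
#' derived with [derive_thresholds()].
#' @name classification
NULL

.hc_table_thresholds <- list(
  speech_perception = c(mean = 2.4, sd = 1.7),
  hearing_related = c(mean = 2.5, sd = 1.8),
  non_hearing_related = c(mean = 1.8, sd = 1.3))

.hc_hearing_levels <- c("NORMAL", "MILD", "MODERATE", "MODERATELY_SEVERE",
                        "OUT_OF_VALIDATED_RANGE")
.hc_degree_levels <- c("NO", "MILD", "MODERATE", "SEVERE")

#' Better-ear pure-tone average
#'
#' @param left,right numeric length-4 vectors of thresholds (dB HL) at
#'   0.5, 1, 2 and 4 kHz for the left and right ear.  All four
#'   frequencies are required per ear; no imputation is performed.
#' @return The smaller (better) of the two ear means, in dB HL.
#' @examples
#' pta(c(10, 20, 30, 40), c(40, 30, 20, 20))  # min(25, 27.5) = 25
#' @export
pta <- function(left, right) {
  for (ear in list(left, right)) {
    if (length(ear) != 4L || anyNA(ear) || any(!is.finite(ear))) {
      stop("each ear needs finite thresholds at all of 0.5/1/2/4 kHz")
    }
  }
  min(mean(left), mean(right))
}

#' Classify hearing loss from a PTA value
#'
#' @param pta_value better-ear PTA in dB HL (vectorized).
#' @return Factor with levels `NORMAL`, `MILD`, `MODERATE`,
#'   `MODERATELY_SEVERE`, `OUT_OF_VALIDATED_RANGE`.
#' @examples
#' classify_hearing(c(15, 30, 60))
#' @export
classify_hearing <- function(pta_value) {
  if (any(!is.finite(pta_value))) stop("PTA must be finite")
  out <- cut(pta_value, breaks = c(-Inf, 20, 35, 50, 65, Inf),
             labels = .hc_hearing_levels, right = FALSE)
  factor(as.character(out), levels = .hc_hearing_levels)
}

#' Reference disability-degree thresholds
#'
#' The published mean/SD pairs per score type: speech perception
#' (M 2.4, SD 1.7), hearing-related (M 2.5, SD 1.8), non-hearing-related
#' (M 1.8, SD 1.3), giving cut points 0.7/2.4/4.1, 0.7/2.5/4.3 and
#' 0.5/1.8/3.1 respectively.
#'
#' @param score_type one of `"hearing_related"`, `"non_hearing_related"`,
#'   `"speech_perception"`.
#' @return A `hc_thresholds` object.
#' @export
published_thresholds <- function(score_type = c("hearing_related",
                                            "non_hearing_related",
                                            "speech_perception")) {
  score_type <- match.arg(score_type)
  p <- .hc_table_thresholds[[score_type]]
  structure(list(score_type = score_type, mean = unname(p["mean"]),
                 sd = unname(p["sd"]), source = "PUBLISHED"),
            class = "hc_thresholds")
}

#' Derive disability thresholds from a score distribution
#'
#' @param scores numeric vector of normalized scores (0--10).
#' @param score_type score-group name the thresholds will apply to.
#' @return A `hc_thresholds` object with the sample mean and sample
#'   (n-1) standard deviation, `source = "COHORT_DERIVED"`.
#' @export
derive_thresholds <- function(scores,
                              score_type = c("hearing_related",
                                             "non_hearing_related",
                                             "speech_perception")) {
  score_type <- match.arg(score_type)
  scores <- scores[is.finite(scores)]
  if (length(scores) < 2L) stop("need at least 2 finite scores")
  s <- stats::sd(scores)
  if (s == 0) stop("degenerate score distribution (zero variance)")
  structure(list(score_type = score_type, mean = mean(scores), sd = s,
                 source = "COHORT_DERIVED"),
            class = "hc_thresholds")
}

#' Cut points of a threshold set
#'
#' @param thresholds a `hc_thresholds` object.
#' @return Numeric vector `c(lower = M - SD, mid = M, upper = M + SD)`.
#' @export
threshold_cuts <- function(thresholds) {
  stopifnot(inherits(thresholds, "hc_thresholds"))
  c(lower = thresholds$mean - thresholds$sd,
    mid = thresholds$mean,
    upper = thresholds$mean + thresholds$sd)
}

#' Assign disability degrees from normalized scores
#'
#' Half-open intervals: No `[0, M-SD)`, Mild `[M-SD, M)`, Moderate
#' `[M, M+SD)`, Severe `[M+SD, 10]`.
#'
#' @param score numeric normalized score(s) in `[0, 10]` (`NA` allowed).
#' @param thresholds a `hc_thresholds` object.
#' @return Factor with levels `NO`, `MILD`, `MODERATE`, `SEVERE`.
#' @examples
#' classify_disability(c(4.5, 0.5), published_thresholds("hearing_related"))
#' @export
classify_disability <- function(score, thresholds) {
  cuts <- threshold_cuts(thresholds)
  ok <- is.na(score) | (score >= 0 & score <= 10)
  if (!all(ok)) stop("scores must lie in [0, 10]")
  out <- cut(score, breaks = c(-Inf, cuts, Inf),
             labels = .hc_degree_levels, right = FALSE)
  factor(as.character(out), levels = .hc_degree_levels)
}

#' PTA-category versus score-degree concordance
#'
#' Cross-tabulates the audiometric hearing category against the
#' score-based disability degree over the respondents for whom both are
#' available, and reports the marginal ratios of "no impairment" and
#' "mild" headcounts (score-based over PTA-based).
#'
#' @param cohort an `hc_cohort` with `pta_better` available.
#' @param scores an `hc_scores` data frame for the same cohort.
#' @param thresholds a `hc_thresholds` object (its `score_type` selects
#'   which normalized score column is used).
#' @return List with `table` (contingency matrix, PTA category in rows),
#'   `n`, and `marginal_ratios`.
#' @export
concordance_table <- function(cohort, scores, thresholds) {
  stopifnot(inherits(cohort, "hc_cohort"), inherits(scores, "data.frame"),
            inherits(thresholds, "hc_thresholds"))
  col <- c(hearing_related = "norm_hearing",
           non_hearing_related = "norm_non_hearing",
           speech_perception = "norm_speech")[[thresholds$score_type]]
  m <- merge(cohort$demo[c("id", "pta_better")], scores[c("id", col)],
             by = "id")
  m <- m[is.finite(m$pta_better) & is.finite(m[[col]]), ]
  if (nrow(m) == 0L) stop("no respondent has both a PTA and a valid score")
  ptacat <- classify_hearing(m$pta_better)
  degree <- classify_disability(m[[col]], thresholds)
  tab <- table(pta = ptacat, score = degree)
  no_pta <- sum(ptacat == "NORMAL")
  mild_pta <- sum(ptacat == "MILD")
  ratios <- c(
    no_by_score_over_no_by_pta =
      if (no_pta > 0) sum(degree == "NO") / no_pta else NA_real_,
    mild_by_score_over_mild_by_pta =
      if (mild_pta > 0) sum(degree == "MILD") / mild_pta else NA_real_)
  list(table = tab, n = nrow(m), marginal_ratios = ratios)
}
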