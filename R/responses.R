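#' @title Response coding and cohorts
#' @description
#' Each item is answered on a five-point scale, 0 (no problem) to 4
#' (profound/complete).  Besides the graded values, every item can carry a
#' non-gradable response: "I don't know" (`DK`), "Not applicable" (`NA`),
#' "Not required" (`NR`, set by filter-question gating), or a missing
#' response (empty cell).  A cohort stores one response vector per
#' respondent together with the demographic and audiometric fields the
#' downstream analyses need.
#' @name responses
NULL

.hc_tokens <- c("0", "1", "2", "3", "4", "DK", "NA", "NR", "")

.hc_demo_cols <- c("id", "country", "age", "gender", "hearing_aid_user",
                   "speech_impaired", "pta_better", "pta_worse")

#' Construct a cohort from demographics and a response matrix
#'
#' @param demo data frame with columns `id` (unique, required),
#'   `hearing_aid_user` and `speech_impaired` (logical, required), and
#'   optionally `country`, `age`, `gender`, `pta_better`, `pta_worse`.
#' @param responses character matrix, one row per respondent (same order as
#'   `demo`), one column per bank item id; entries are tokens `"0"`..`"4"`,
#'   `"DK"`, `"NA"`, `"NR"` or `""` (missing).
#' @param bank item bank the responses refer to.
#' @param gated has gating already been applied?  If `FALSE` (default)
#'   [apply_gating()] is run.
#' @return An `hc_cohort` object.
#' @export
new_cohort <- function(demo, responses, bank, gated = FALSE) {
  stopifnot(inherits(bank, "hc_bank"), is.data.frame(demo))
  if (anyDuplicated(demo$id)) stop("duplicate respondent id(s)")
  need <- c("id", "hearing_aid_user", "speech_impaired")
  miss <- setdiff(need, names(demo))
  if (length(miss)) stop("demo lacks column(s): ", paste(miss, collapse = ", "))
  for (col in setdiff(.hc_demo_cols, names(demo))) demo[[col]] <- NA
  demo <- demo[.hc_demo_cols]
  responses <- as.matrix(responses)
  storage.mode(responses) <- "character"
  responses[is.na(responses)] <- ""
  if (!setequal(colnames(responses), bank$items$id)) {
    stop("response columns must be exactly the bank's item ids")
  }
  responses <- responses[, bank$items$id, drop = FALSE]
  if (nrow(responses) != nrow(demo)) stop("demo/responses row mismatch")
  rownames(responses) <- demo$id
  badtok <- matrix(!(responses %in% .hc_tokens), nrow(responses))
  if (any(badtok)) {
    idx <- which(badtok, arr.ind = TRUE)[1, ]
    stop(sprintf("invalid response token '%s' (respondent %s, item %s)",
                 responses[badtok][1], demo$id[idx[1]],
                 colnames(responses)[idx[2]]))
  }
  both <- !is.na(demo$pta_better) & !is.na(demo$pta_worse)
  if (any(both & demo$pta_better > demo$pta_worse)) {
    stop("pta_better exceeds pta_worse for some respondent(s)")
  }
  cohort <- structure(list(demo = demo, responses = responses,
                           bank_version = bank$version),
                      class = "hc_cohort")
  if (gated) cohort else apply_gating(cohort, bank)
}

#' Apply filter-question gating
#'
#' Items `H.87`--`H.90` (hearing-aid benefits) are recorded as
#' "Not required" for respondents who do not use a hearing aid; items
#' `H.42`--`H.48` (voice and speech production) likewise for respondents
#' without speech impairment.  A graded answer found on a gated-off item is
#' overwritten with a warning.  The operation is idempotent.
#'
#' @param cohort an `hc_cohort` (or a single-respondent cohort).
#' @param bank item bank.
#' @return The gated cohort.
#' @export
apply_gating <- function(cohort, bank) {
  stopifnot(inherits(cohort, "hc_cohort"), inherits(bank, "hc_bank"))
  resp <- cohort$responses
  for (g in c("HEARING_AID_USER", "SPEECH_IMPAIRMENT")) {
    ids <- bank$items$id[bank$items$gate == g]
    open <- if (g == "HEARING_AID_USER") cohort$demo$hearing_aid_user
            else cohort$demo$speech_impaired
    open <- isTRUE_vec(open)
    closed <- !open
    if (!any(closed)) next
    block <- resp[closed, ids, drop = FALSE]
    graded <- block %in% as.character(0:4)
    if (any(graded)) {
      idx <- which(matrix(graded, nrow(block)), arr.ind = TRUE)
      warning(sprintf(
        "graded answer(s) on gated-off items overwritten to NR (e.g. respondent %s, item %s)",
        rownames(block)[idx[1, 1]], ids[idx[1, 2]]), call. = FALSE)
    }
    block[] <- "NR"
    resp[closed, ids] <- block
  }
  cohort$responses <- resp
  cohort
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Non-gradable rate of an item
#'
#' The proportion of respondents whose response to `item` is any of
#' "I don't know", "Not applicable", "Not required", or missing.
#'
#' @param cohort an `hc_cohort`.
#' @param item item id, e.g. `"H.88"`.
#' @return Proportion in `[0, 1]`.
#' @export
non_gradable_rate <- function(cohort, item) {
  stopifnot(inherits(cohort, "hc_cohort"))
  if (!item %in% colnames(cohort$responses)) stop("unknown item id: ", item)
  if (nrow(cohort$responses) == 0L) stop("empty cohort")
  v <- cohort$responses[, item]
  mean(!(v %in% as.character(0:4)))
}

#' Graded responses as a numeric matrix
#'
#' @param cohort an `hc_cohort`.
#' @param items item ids (default: all bank items in the cohort).
#' @return Numeric matrix of grades 0--4 with `NA` for every non-gradable
#'   response; rows are respondents.
#' @export
response_grades <- function(cohort, items = NULL) {
  stopifnot(inherits(cohort, "hc_cohort"))
  m <- cohort$responses
  if (!is.null(items)) {
    if (!all(items %in% colnames(m))) stop("unknown item id(s)")
    m <- m[, items, drop = FALSE]
  }
  out <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m),
                                 dimnames = dimnames(m)))
  out
}

#' Read a cohort from CSV
#'
#' Expected columns: `id`, optional demographics (`country`, `age`,
#' `gender`, `pta_better`, `pta_worse`), `hearing_aid_user`,
#' `speech_impaired` (logical or 0/1), and one column per item id.  Cells
#' hold `0`..`4`, `DK`, `NA`, `NR`, or are empty (missing).  Gating is
#' applied after reading; a wholly absent item column is read as missing
#' with a warning.
#'
#' @param csv_source path to the CSV file.
#' @param bank item bank.
#' @return An `hc_cohort`.
#' @export
read_cohort <- function(csv_source, bank) {
  stopifnot(inherits(bank, "hc_bank"))
  df <- utils::read.csv(csv_source, colClasses = "character",
                        na.strings = NULL, check.names = FALSE)
  if (!"id" %in% names(df)) stop("cohort CSV lacks an 'id' column")
  item_ids <- bank$items$id
  absent <- setdiff(item_ids, names(df))
  if (length(absent)) {
    warning("item column(s) absent, read as MISSING: ",
            paste(absent, collapse = ", "), call. = FALSE)
    for (a in absent) df[[a]] <- ""
  }
  resp <- as.matrix(df[item_ids])
  bad <- !(resp %in% .hc_tokens)
  if (any(bad)) {
    idx <- which(matrix(bad, nrow(resp)), arr.ind = TRUE)[1, ]
    stop(sprintf("malformed response token '%s' at row %d, column %s",
                 resp[bad][1], idx[1], item_ids[idx[2]]))
  }
  as_log <- function(x) {
    if (is.null(x)) return(NA)
    out <- rep(NA, length(x))
    out[x %in% c("TRUE", "true", "1", "yes")] <- TRUE
    out[x %in% c("FALSE", "false", "0", "no")] <- FALSE
    out
  }
  as_num <- function(x) if (is.null(x)) NA_real_ else
    suppressWarnings(as.numeric(ifelse(x == "", NA, x)))
  demo <- data.frame(
    id = df$id,
    country = if (is.null(df$country)) NA_character_ else
      ifelse(df$country == "", NA, df$country),
    age = as_num(df$age),
    gender = if (is.null(df$gender)) NA_character_ else
      ifelse(df$gender == "", NA, df$gender),
    hearing_aid_user = as_log(df$hearing_aid_user),
    speech_impaired = as_log(df$speech_impaired),
    pta_better = as_num(df$pta_better),
    pta_worse = as_num(df$pta_worse),
    stringsAsFactors = FALSE)
  if (anyNA(demo$hearing_aid_user) || anyNA(demo$speech_impaired)) {
    stop("hearing_aid_user / speech_impaired must be present for every row")
  }
  new_cohort(demo, resp, bank)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: reading the written file back yields an
#' identical cohort.
#'
#' @param cohort an `hc_cohort`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "hc_cohort"))
  df <- cbind(cohort$demo, as.data.frame(cohort$responses,
                                         stringsAsFactors = FALSE))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.hc_cohort <- function(x, ...) {
  cat("HEAR-COMMAND cohort: ", nrow(x$demo), " respondents, bank version ",
      x$bank_version, "\n", sep = "")
  cat("  hearing-aid users: ", sum(isTRUE_vec(x$demo$hearing_aid_user)),
      ", speech-impaired: ", sum(isTRUE_vec(x$demo$speech_impaired)),
      "\n", sep = "")
  invisible(x)
}
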