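#' @title HEAR-COMMAND item bank
#' @description
#' The item bank encodes the structure of the 90-item instrument: the ICF
#' domain (`BF` body functions, `AP` activities and participation, `EF`
#' environmental factors) and linked ICF category codes of every item, the
#' seven construct labels `A`--`G` derived from exploratory factor analysis,
#' membership in the three outcome-score groups, facilitator polarity
#' (items whose numeric responses are mirrored before aggregation), and
#' filter-question gating (item blocks administered only to speech-impaired
#' respondents or hearing-aid users).
#'
#' Memberships are frozen in a canonical JSON configuration shipped with the
#' package; [load_item_bank()] validates every structural invariant and
#' refuses configurations that break them.
#' @name item_bank
NULL

# group-size invariants of the canonical instrument
.hc_expected <- list(
  n_items = 90L,
  label_counts = c(A = 20L, B = 18L, C = 4L, D = 6L, E = 13L, F = 9L, G = 8L),
  n_hearing = 37L, n_non_hearing = 41L, n_speech = 32L, n_scored = 78L,
  speech_excluded = c("H.25", "H.26", "H.27", "H.29", "H.31"),
  mirrored = sprintf("H.%d", 75:80),
  speech_gate = sprintf("H.%d", 42:48),
  aid_gate = sprintf("H.%d", 87:90)
)

#' Load and validate an item-bank configuration
#'
#' Reads an item-bank JSON configuration (one record per item) and validates
#' the full set of structural invariants: 90 unique ids `H.1`--`H.90`,
#' mirrored polarity exactly on `H.75`--`H.80`, score-group memberships
#' consistent with the construct labels (hearing-related = labels A, C, E;
#' non-hearing-related = B, D, F, G; speech perception = hearing-related
#' minus the five non-speech-target items), group sizes 37/41/32/78, and
#' gating restricted to `H.42`--`H.48` (speech impairment) and
#' `H.87`--`H.90` (hearing-aid use).
#'
#' @param config_source path to a JSON configuration, or `NULL` (default)
#'   for the canonical bank shipped with the package.
#' @return An object of class `hc_bank`: a list with `items` (a data frame,
#'   one row per item, with list-column `icf_codes`), `version` and
#'   `language_tag`.
#' @examples
#' bank <- load_item_bank()
#' nrow(bank$items)
#' @export
load_item_bank <- function(config_source = NULL) {
  if (is.null(config_source)) {
    config_source <- system.file("extdata", "item_bank.json",
                                 package = "hearcommand", mustWork = TRUE)
  }
  raw <- jsonlite::read_json(config_source)
  if (is.null(raw$items)) stop("item-bank config has no 'items' field")
  req <- c("id", "icf_domain", "icf_codes", "construct_label", "efa_factor",
           "polarity", "in_hearing_related", "in_non_hearing_related",
           "in_speech_perception", "gate", "short_concept")
  items <- lapply(raw$items, function(it) {
    miss <- setdiff(req, names(it))
    if (length(miss)) {
      stop("item record ", if (!is.null(it$id)) it$id else "<no id>",
           " missing field(s): ", paste(miss, collapse = ", "))
    }
    it
  })
  df <- data.frame(
    id = vapply(items, function(x) as.character(x$id), ""),
    icf_domain = vapply(items, function(x) as.character(x$icf_domain), ""),
    construct_label =
      vapply(items, function(x) as.character(x$construct_label), ""),
    efa_factor = vapply(items, function(x) {
      if (identical(x$efa_factor, "NONE")) NA_integer_
      else as.integer(x$efa_factor)
    }, 1L),
    polarity = vapply(items, function(x) as.character(x$polarity), ""),
    in_hearing_related =
      vapply(items, function(x) isTRUE(x$in_hearing_related), TRUE),
    in_non_hearing_related =
      vapply(items, function(x) isTRUE(x$in_non_hearing_related), TRUE),
    in_speech_perception =
      vapply(items, function(x) isTRUE(x$in_speech_perception), TRUE),
    gate = vapply(items, function(x) as.character(x$gate), ""),
    short_concept = vapply(items, function(x) as.character(x$short_concept), ""),
    stringsAsFactors = FALSE
  )
  df$icf_codes <- lapply(items, function(x) unlist(x$icf_codes) %||% character(0))
  bank <- structure(
    list(items = df,
         version = raw$version %||% "unversioned",
         language_tag = raw$language_tag %||% "und"),
    class = "hc_bank")
  validate_item_bank(bank)
  bank
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate an item bank against every structural invariant
#'
#' @param bank an `hc_bank` object.
#' @return `bank`, invisibly, if valid; otherwise an error listing every
#'   violated invariant.
#' @export
validate_item_bank <- function(bank) {
  stopifnot(inherits(bank, "hc_bank"))
  it <- bank$items
  exp <- .hc_expected
  bad <- character(0)
  note <- function(msg) bad <<- c(bad, msg)

  if (nrow(it) != exp$n_items) {
    note(sprintf("%d items, expected %d", nrow(it), exp$n_items))
  }
  if (anyDuplicated(it$id)) {
    note(paste("duplicate item id(s):",
               paste(unique(it$id[duplicated(it$id)]), collapse = ", ")))
  }
  want_ids <- sprintf("H.%d", seq_len(exp$n_items))
  if (nrow(it) == exp$n_items && !setequal(it$id, want_ids)) {
    note("item ids are not exactly H.1..H.90")
  }
  if (!all(it$icf_domain %in% c("BF", "AP", "EF"))) {
    note("icf_domain outside {BF, AP, EF}")
  }
  if (!all(it$construct_label %in% c(LETTERS[1:7], "NONE"))) {
    note("unknown construct label")
  }
  if (!all(it$polarity %in% c("STANDARD", "MIRRORED"))) {
    note("unknown polarity value")
  }
  mir <- it$id[it$polarity == "MIRRORED"]
  if (!setequal(mir, exp$mirrored)) {
    note("MIRRORED polarity must be exactly H.75..H.80")
  }
  # score-group membership must follow the construct labels
  hear <- it$construct_label %in% c("A", "C", "E")
  nonh <- it$construct_label %in% c("B", "D", "F", "G")
  if (!identical(it$in_hearing_related, hear)) {
    note("in_hearing_related inconsistent with labels A/C/E")
  }
  if (!identical(it$in_non_hearing_related, nonh)) {
    note("in_non_hearing_related inconsistent with labels B/D/F/G")
  }
  sp <- hear & !(it$id %in% exp$speech_excluded)
  if (!identical(it$in_speech_perception, sp)) {
    note("in_speech_perception must be hearing-related minus the 5 non-speech items")
  }
  cnt <- table(factor(it$construct_label, levels = LETTERS[1:7]))
  if (!all(cnt == exp$label_counts)) {
    note(sprintf("label counts %s, expected %s",
                 paste(cnt, collapse = "/"),
                 paste(exp$label_counts, collapse = "/")))
  }
  if (sum(it$in_hearing_related) != exp$n_hearing ||
      sum(it$in_non_hearing_related) != exp$n_non_hearing ||
      sum(it$in_speech_perception) != exp$n_speech) {
    note("score-group sizes differ from 37/41/32")
  }
  if (!setequal(it$id[it$gate == "SPEECH_IMPAIRMENT"], exp$speech_gate)) {
    note("SPEECH_IMPAIRMENT gate must be exactly H.42..H.48")
  }
  if (!setequal(it$id[it$gate == "HEARING_AID_USER"], exp$aid_gate)) {
    note("HEARING_AID_USER gate must be exactly H.87..H.90")
  }
  labelled <- it$construct_label != "NONE"
  if (any(labelled & lengths(it$icf_codes) == 0)) {
    note("labelled item without an ICF category code")
  }
  if (length(bad)) {
    stop("item-bank validation failed:\n  - ",
         paste(bad, collapse = "\n  - "), call. = FALSE)
  }
  invisible(bank)
}

#' Item ids belonging to a score group
#'
#' @param bank an `hc_bank`.
#' @param group one of `"hearing_related"` (37 items, labels A, C, E),
#'   `"non_hearing_related"` (41 items, labels B, D, F, G),
#'   `"speech_perception"` (32 items, hearing-related minus the five items
#'   whose target sounds are non-speech), or `"all_scored"` (the 78
#'   labelled items).
#' @return Character vector of item ids in ascending item-number order.
#' @export
items_in_group <- function(bank, group) {
  stopifnot(inherits(bank, "hc_bank"))
  group <- match.arg(group, c("hearing_related", "non_hearing_related",
                              "speech_perception", "all_scored"))
  it <- bank$items
  keep <- switch(group,
    hearing_related = it$in_hearing_related,
    non_hearing_related = it$in_non_hearing_related,
    speech_perception = it$in_speech_perception,
    all_scored = it$construct_label != "NONE")
  ids <- it$id[keep]
  ids[order(item_number(ids))]
}

#' Numeric part of an item id
#'
#' @param ids character item ids like `"H.17"`.
#' @return Integer vector of item numbers.
#' @export
item_number <- function(ids) as.integer(sub("^H\\.", "", ids))

#' Serialize an item bank back to JSON
#'
#' Writing then re-loading the canonical bank is the identity.
#'
#' @param bank an `hc_bank`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_item_bank <- function(bank, path) {
  stopifnot(inherits(bank, "hc_bank"))
  it <- bank$items
  items <- lapply(seq_len(nrow(it)), function(i) {
    list(
      id = it$id[i],
      icf_domain = it$icf_domain[i],
      icf_codes = it$icf_codes[[i]],
      construct_label = it$construct_label[i],
      efa_factor = if (is.na(it$efa_factor[i])) "NONE" else it$efa_factor[i],
      polarity = it$polarity[i],
      in_hearing_related = it$in_hearing_related[i],
      in_non_hearing_related = it$in_non_hearing_related[i],
      in_speech_perception = it$in_speech_perception[i],
      gate = it$gate[i],
      short_concept = it$short_concept[i])
  })
  jsonlite::write_json(
    list(version = bank$version, language_tag = bank$language_tag,
         items = items),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.hc_bank <- function(x, ...) {
  it <- x$items
  cat("HEAR-COMMAND item bank (version ", x$version, ", ",
      nrow(it), " items)\n", sep = "")
  cat("  hearing-related: ", sum(it$in_hearing_related),
      "  non-hearing-related: ", sum(it$in_non_hearing_related),
      "  speech perception: ", sum(it$in_speech_perception), "\n", sep = "")
  cat("  gated: H.42-H.48 (speech impairment), H.87-H.90 (hearing-aid use)\n")
  invisible(x)
}
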