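test_that("mirroring reflects the scale and is an involution", {
  expect_identical(mirror_value(4L), 0L)
  expect_identical(mirror_value(3L), 1L)
  expect_identical(mirror_value(2L), 2L)
  expect_identical(mirror_value(0L), 4L)
  for (g in 0:4) expect_identical(mirror_value(mirror_value(g)), g)
  expect_error(mirror_value(5L))
  expect_error(mirror_value(NA_integer_))
})

test_that("coded values respect item polarity and non-gradable kinds", {
  expect_identical(coded_value("H.76", 4, hc_test_bank), 0L)   # facilitator
  expect_identical(coded_value("H.83", 4, hc_test_bank), 4L)   # barrier
  expect_identical(coded_value("H.37", "DK", hc_test_bank), NA_integer_)
  expect_identical(coded_value("H.37", "NR", hc_test_bank), NA_integer_)
  expect_identical(coded_value("H.37", "", hc_test_bank), NA_integer_)
  expect_error(coded_value("H.99", 1, hc_test_bank), "unknown item")
})

test_that("normalization coefficients match the published constants", {
  expect_equal(normalization_coefficient(37, "published"), 0.067)
  expect_equal(normalization_coefficient(41, "published"), 0.061)
  expect_equal(normalization_coefficient(32, "published"), 0.0782)
  expect_equal(normalization_coefficient(37, "exact"), 10 / 148)
  expect_equal(normalization_coefficient(41, "exact"), 10 / 164)
  expect_equal(normalization_coefficient(32, "exact"), 10 / 128)
  expect_error(normalization_coefficient(36, "published"), "36")
})

test_that("worked fixture raw scores match the hand-computed values", {
  fx <- generate_worked_fixture(hc_test_bank)
  sc <- score_cohort(fx$cohort, hc_test_bank, score_policy("prorated"))
  expect_equal(sc$raw_hearing, fx$expected$raw_hearing)
  expect_equal(sc$raw_non_hearing, fx$expected$raw_non_hearing)
  expect_equal(sc$raw_speech, fx$expected$raw_speech)
  # floor and top of the normalized scale
  expect_equal(unlist(sc[1, c("norm_hearing", "norm_non_hearing",
                              "norm_speech")], use.names = FALSE),
               c(0, 0, 0))
  expect_equal(unlist(sc[2, c("norm_hearing", "norm_non_hearing",
                              "norm_speech")], use.names = FALSE),
               c(10, 10, 10))
  # half-coverage respondent is invalid under the default policy
  expect_false(sc$valid_hearing[6])
  expect_true(sc$coverage_hearing[6] < 0.6)
})

test_that("published mode reproduces printed numbers at full coverage only", {
  fx <- generate_worked_fixture(hc_test_bank)
  sc <- score_cohort(fx$cohort, hc_test_bank, score_policy("published"))
  # raw hearing 37 for the mid-scale respondent: 37 * 0.067 = 2.479
  expect_equal(sc$norm_hearing[3], 37 * 0.067)
  # maximal hardship: hearing 148 * 0.067 = 9.916; the rounded
  # coefficients overshoot for the other two groups, capped at 10
  expect_equal(sc$norm_hearing[2], 9.916)
  expect_equal(sc$norm_non_hearing[2], 10)
  expect_equal(sc$norm_speech[2], 10)
  # incomplete coverage: no published score
  expect_true(is.na(sc$norm_hearing[6]))
  expect_false(sc$valid_hearing[6])
})

test_that("a 37-item hearing raw of 67 normalizes to 4.489 (published)", {
  # arithmetic oracle: 67 * 0.067 = 4.489, reported as 4.49
  bank <- hc_test_bank
  hr <- items_in_group(bank, "hearing_related")
  resp <- matrix("0", 1, 90, dimnames = list("P1", bank$items$id))
  resp[1, bank$items$id[bank$items$polarity == "MIRRORED"]] <- "4"
  # grade pattern summing to 67: 16 items at 4, 1 at 3, the rest 0
  resp[1, hr[1:16]] <- "4"
  resp[1, hr[17]] <- "3"
  demo <- data.frame(id = "P1", hearing_aid_user = FALSE,
                     speech_impaired = FALSE)
  co <- suppressWarnings(new_cohort(demo, resp, bank))
  sc <- score_cohort(co, bank, score_policy("published"))
  expect_equal(sc$raw_hearing, 67)
  expect_equal(sc$norm_hearing, 4.489)
  expect_equal(round(sc$norm_hearing, 2), 4.49)
})

test_that("prorated equals exact at full coverage; published stays close", {
  g <- generate_cohort(generator_config(seed = 3))
  co <- g$cohort
  # force full coverage: overwrite non-graded cells on ungated items
  resp <- co$responses
  open <- hc_test_bank$items$gate == "NONE"
  block <- resp[, open]
  block[!(block %in% as.character(0:4))] <- "2"
  resp[, open] <- block
  co$responses <- resp
  sc_pro <- score_cohort(co, hc_test_bank, score_policy("prorated"))
  sc_ex <- score_cohort(co, hc_test_bank, score_policy("exact"))
  sc_pub <- score_cohort(co, hc_test_bank, score_policy("published"))
  for (cn in c("norm_hearing", "norm_non_hearing", "norm_speech")) {
    expect_equal(sc_pro[[cn]], sc_ex[[cn]], tolerance = 1e-12)
    # rounded published coefficients deviate at most 0.0008 * 148 = 0.118
    expect_true(max(abs(sc_pub[[cn]] - sc_ex[[cn]])) <= 0.12)
  }
})

test_that("scores are monotone in coded values and bounded in [0, 10]", {
  set.seed(42)
  bank <- hc_test_bank
  for (rep in 1:5) {
    resp <- matrix(as.character(sample(0:4, 90, replace = TRUE)), 1, 90,
                   dimnames = list("M1", bank$items$id))
    demo <- data.frame(id = "M1", hearing_aid_user = TRUE,
                       speech_impaired = TRUE)
    co <- new_cohort(demo, resp, bank)
    base <- score_cohort(co, bank, score_policy("prorated"))
    expect_true(all(unlist(base[c("norm_hearing", "norm_non_hearing",
                                  "norm_speech")]) >= 0))
    expect_true(all(unlist(base[c("norm_hearing", "norm_non_hearing",
                                  "norm_speech")]) <= 10))
    # bump one random scored item by +1 in coded terms
    scored <- items_in_group(bank, "all_scored")
    it <- sample(scored, 1)
    mirrored <- bank$items$polarity[bank$items$id == it] == "MIRRORED"
    g <- as.integer(resp[1, it])
    coded <- if (mirrored) 4L - g else g
    if (coded == 4L) next
    resp2 <- resp
    resp2[1, it] <- as.character(if (mirrored) g - 1L else g + 1L)
    co2 <- new_cohort(demo, resp2, bank)
    bumped <- score_cohort(co2, bank, score_policy("prorated"))
    for (cn in c("norm_hearing", "norm_non_hearing", "norm_speech")) {
      expect_true(bumped[[cn]] >= base[[cn]])
    }
  }
})

test_that("speech score ignores non-speech hearing items", {
  bank <- hc_test_bank
  resp <- matrix("1", 1, 90, dimnames = list("S1", bank$items$id))
  demo <- data.frame(id = "S1", hearing_aid_user = FALSE,
                     speech_impaired = FALSE)
  co <- suppressWarnings(new_cohort(demo, resp, bank))
  base <- score_cohort(co, bank, score_policy("prorated"))
  resp2 <- resp
  resp2[1, "H.25"] <- "DK"    # excluded from speech perception
  co2 <- suppressWarnings(new_cohort(demo, resp2, bank))
  after <- score_cohort(co2, bank, score_policy("prorated"))
  expect_equal(after$raw_speech, base$raw_speech)
  expect_true(after$raw_hearing < base$raw_hearing)
})

test_that("score_respondent selects one row by id or index", {
  g <- generate_cohort(generator_config(seed = 2))
  co <- g$cohort
  all <- score_cohort(co, hc_test_bank)
  one <- score_respondent(co$demo$id[5], hc_test_bank, cohort = co)
  expect_equal(one$norm_hearing, all$norm_hearing[5])
  expect_error(score_respondent("nobody", hc_test_bank, cohort = co))
})
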