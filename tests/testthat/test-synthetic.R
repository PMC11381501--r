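test_that("generation is reproducible and seed-sensitive", {
  g1 <- generate_cohort(generator_config(seed = 9))
  g2 <- generate_cohort(generator_config(seed = 9))
  g3 <- generate_cohort(generator_config(seed = 10))
  expect_identical(g1$cohort$responses, g2$cohort$responses)
  expect_identical(g1$cohort$demo, g2$cohort$demo)
  expect_identical(g1$truth$latent, g2$truth$latent)
  expect_false(identical(g1$cohort$responses, g3$cohort$responses))
})

test_that("subgroup marginals are controlled exactly", {
  g <- generate_cohort(generator_config(seed = 1))
  co <- g$cohort
  expect_equal(nrow(co$demo), 215)
  expect_equal(sum(co$demo$pta_better < 20), 58)
  expect_equal(sum(co$demo$hearing_aid_user), 70)
  expect_equal(sum(co$demo$speech_impaired), 11)
  expect_equal(sum(g$truth$class != "NH") / 215, 157 / 215)
  # unaided mild 47, aided moderately severe 24
  expect_equal(sum(g$truth$class == "MI" & !g$truth$aided), 47)
  expect_equal(sum(g$truth$class == "MS" & g$truth$aided), 24)
  # PTA inside its class band
  bands <- list(NH = c(-2, 20), MI = c(20, 35), MO = c(35, 50),
                MS = c(50, 65))
  for (cl in names(bands)) {
    v <- co$demo$pta_better[g$truth$class == cl]
    expect_true(all(v >= bands[[cl]][1] & v < bands[[cl]][2]))
  }
  expect_true(all(co$demo$pta_worse >= co$demo$pta_better))
  # country mix
  expect_equal(sort(as.integer(table(co$demo$country))), sort(c(89, 54, 72)))
})

test_that("non-gradable injection hits its marginal target", {
  cfg <- generator_config(seed = 1)
  g <- generate_cohort(cfg)
  base_items <- setdiff(
    hc_test_bank$items$id[hc_test_bank$items$gate == "NONE"],
    names(cfg$elevated_rates))
  expect_length(base_items, 72)
  rates <- vapply(base_items, function(it) non_gradable_rate(g$cohort, it), 0)
  expect_true(abs(mean(rates) - 0.042) < 0.015)
  # elevated items really are elevated
  ev <- vapply(names(cfg$elevated_rates),
               function(it) non_gradable_rate(g$cohort, it), 0)
  expect_true(all(ev > 0.08))
})

test_that("hearing severity raises hearing-related scores", {
  worse <- vapply(1:20, function(s) {
    g <- generate_cohort(generator_config(seed = s))
    sc <- score_cohort(g$cohort, hc_test_bank)
    nh <- g$truth$class == "NH"
    unaided_hl <- g$truth$class != "NH" & !g$truth$aided
    mean(sc$norm_hearing[nh], na.rm = TRUE) <
      mean(sc$norm_hearing[unaided_hl], na.rm = TRUE)
  }, TRUE)
  expect_true(all(worse))
})

test_that("degenerate zero-noise, zero-effect config collapses the cohort", {
  cfg <- generator_config(
    seed = 1,
    group_effects = matrix(0, 4, 2,
                           dimnames = list(c("NH", "MI", "MO", "MS"),
                                           c("hearing", "non_hearing"))),
    primary_loadings = rep(1e-12, 90),   # no construct signal
    ordinal_thresholds = matrix(rep(c(10, 11, 12, 13), each = 90), 90, 4),
    nongradable_rate = 0, nongradable_jitter_sd = 0,
    elevated_rates = numeric(0), n_speech_impaired = 0)
  g <- generate_cohort(cfg)
  graded <- g$cohort$responses[, hc_test_bank$items$gate == "NONE"]
  # latent values can never clear a threshold at 10: all grades zero
  # (facilitators reflected to 4)
  facil <- colnames(graded) %in% sprintf("H.%d", 75:80)
  expect_true(all(graded[, !facil] == "0"))
  expect_true(all(graded[, facil] == "4"))
})

test_that("infeasible configurations are rejected", {
  expect_error(generator_config(country_mix = c(Germany = 1, Egypt = 1,
                                                USA = 1)),
               "country_mix")
  expect_error(generator_config(
    construct_correlations = matrix(1, 7, 7)))
  expect_error(generator_config(
    ordinal_thresholds = matrix(rep(c(2, 1, 3, 4), each = 90), 90, 4)))
})

test_that("worked fixture scores agree with the shipped expectations", {
  fx <- generate_worked_fixture(hc_test_bank)
  expect_equal(nrow(fx$cohort$demo), 6)
  sc <- score_cohort(fx$cohort, hc_test_bank, score_policy("prorated"))
  expect_equal(sc$raw_hearing, fx$expected$raw_hearing)
  expect_equal(sc$raw_non_hearing, fx$expected$raw_non_hearing)
  expect_equal(sc$raw_speech, fx$expected$raw_speech)
  # the answered-but-gated H.87 of respondent W4 is Not Required
  expect_identical(unname(fx$cohort$responses["W4", "H.87"]), "NR")
  # strict mode: the 50%-coverage respondent has no valid score
  strict <- score_cohort(fx$cohort, hc_test_bank, score_policy("published"))
  expect_false(strict$valid_hearing[6])
  expect_true(is.na(strict$norm_hearing[6]))
})
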