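test_that("floor/ceiling effects use a strict 15% rule over all respondents", {
  bank <- hc_test_bank
  n <- 100
  co <- uniform_cohort(n, grade = "2")
  resp <- co$responses
  resp[1:16, "H.5"] <- "0"    # 16% at the floor
  resp[1:15, "H.6"] <- "0"    # exactly 15%: no effect
  resp[1:20, "H.7"] <- "4"    # 20% at the ceiling
  resp[, "H.8"] <- "DK"       # nobody graded
  co$responses <- resp
  d <- describe_items(co, bank)
  rowf <- function(id) d[d$item_id == id, ]
  expect_true(rowf("H.5")$floor_present)
  expect_false(rowf("H.6")$floor_present)
  expect_true(rowf("H.7")$ceiling_present)
  expect_false(rowf("H.5")$ceiling_present)
  # constant item: sd 0, median 2
  expect_equal(rowf("H.10")$sd, 0)
  expect_equal(rowf("H.10")$median, 2)
  expect_equal(rowf("H.10")$mean, 2)
  # ungraded item flagged undefined
  expect_true(rowf("H.8")$undefined)
  expect_true(is.na(rowf("H.8")$mean))
  # non-gradable denominators are logged separately
  expect_equal(rowf("H.8")$n_non_gradable, n)
  expect_equal(rowf("H.87")$n_non_gradable, n)  # gated off for everyone
})

test_that("alpha is 1 for duplicated items and matches the closed form", {
  set.seed(1)
  x <- rnorm(50)
  m <- cbind(x, x, x)
  expect_equal(cronbach_alpha(m)$alpha, 1)
  # closed form k*r / (1 + (k-1)*r) for equicorrelated items
  k <- 3; rho <- 0.5
  m2 <- compound_symmetric(5000, k, rho, seed = 2)
  a <- cronbach_alpha(m2)
  expect_equal(a$alpha, k * rho / (1 + (k - 1) * rho), tolerance = 0.02)
  expect_equal(a$n_complete_respondents, 5000)
  expect_length(a$item_total_correlations, k)
})

test_that("alpha properties: rescaling invariance, duplication, deletion", {
  set.seed(3)
  m <- compound_symmetric(200, 5, 0.4, seed = 3)
  a0 <- cronbach_alpha(m)$alpha
  # invariant under linear rescaling with a (common) positive slope and
  # arbitrary per-item shifts; the covariance-based alpha is deliberately
  # not invariant to item-specific slopes
  m_scaled <- sweep(2.5 * m, 2, c(-1, 4, 0, 2, -7), "+")
  expect_equal(cronbach_alpha(m_scaled)$alpha, a0, tolerance = 1e-12)
  # duplicating an item never decreases alpha
  expect_true(cronbach_alpha(cbind(m, m[, 1]))$alpha >= a0)
  # listwise deletion is logged
  m_na <- m
  m_na[1:10, 1] <- NA
  expect_equal(cronbach_alpha(m_na)$n_complete_respondents, 190)
  # guard rails
  expect_error(cronbach_alpha(m[, 1, drop = FALSE]), "at least 2")
  expect_error(cronbach_alpha(matrix(1, 50, 3)), "zero total")
  expect_error(cronbach_alpha(m[1, , drop = FALSE]), "fewer than 2")
})

test_that("Mann-Whitney agrees with brute-force enumeration for n1,n2 <= 6", {
  set.seed(4)
  cases <- list(
    list(a = c(1, 2, 3), b = c(4, 5, 6)),       # complete separation
    list(a = c(1, 2), b = c(1, 2))              # full ties
  )
  for (i in 1:20) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    pool <- sample(1:5, n1 + n2, replace = TRUE)  # many ties
    cases[[length(cases) + 1]] <- list(a = pool[1:n1],
                                       b = pool[(n1 + 1):(n1 + n2)])
  }
  for (cs in cases) {
    got <- mann_whitney(cs$a, cs$b)
    want <- brute_force_mw(cs$a, cs$b)
    expect_equal(got$statistic, want$u)
    expect_equal(got$p_value, want$p, tolerance = 1e-12)
  }
  # the two named examples
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$statistic, 0)
  expect_equal(mann_whitney(c(1, 2), c(1, 2))$statistic, 2)
  expect_equal(mann_whitney(c(1, 2), c(1, 2))$p_value, 1)
})

test_that("Mann-Whitney large-sample branch matches stats::wilcox.test", {
  set.seed(5)
  a <- rnorm(40); b <- rnorm(45, 0.4)
  got <- mann_whitney(a, b)            # n1*n2 > 400: normal approximation
  ref <- stats::wilcox.test(a, b, correct = TRUE, exact = FALSE)
  expect_equal(got$u1, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-9)
  expect_match(got$method, "normal approximation")
  # U bounds and degenerate input
  expect_true(got$statistic >= 0 && got$statistic <= 40 * 45)
  expect_equal(mann_whitney(rep(2, 5), rep(2, 7))$p_value, 1)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("KMO: algebraic identity at p = 2, simulation oracles elsewhere", {
  # for two variables the anti-image partial correlation equals -r,
  # so KMO = r^2 / (r^2 + r^2) = 0.5 whenever r != 0
  for (r in c(0.2, 0.5, -0.7)) {
    R <- matrix(c(1, r, r, 1), 2, 2)
    expect_equal(kmo(R)$kmo, 0.5, tolerance = 1e-12)
  }
  # strong single factor: high adequacy
  set.seed(6)
  f <- rnorm(500)
  x <- sapply(1:10, function(i) 0.8 * f + sqrt(1 - 0.64) * rnorm(500))
  expect_true(kmo(cor(x))$kmo > 0.8)
  # near-identity correlations: low adequacy
  y <- matrix(rnorm(500 * 10), 500, 10)
  expect_true(kmo(cor(y))$kmo < 0.6)
  # singular input advises regularization
  Rs <- matrix(1, 3, 3)
  expect_error(kmo(Rs), "regularize")
})

test_that("Bartlett's sphericity: df formula and arithmetic oracle", {
  # p = 78 gives df = 3003; identity matrix gives X2 = 0, p = 1
  R78 <- diag(78)
  res <- bartlett_sphericity(R78, n = 215)
  expect_equal(res$df, 3003)
  expect_equal(res$chi2, 0)
  expect_equal(res$p_value, 1)
  # 3x3 equicorrelated r = 0.5: det = (1-r)^2 (1+2r) = 0.5 exactly
  R3 <- matrix(0.5, 3, 3); diag(R3) <- 1
  n <- 100
  want <- -(n - 1 - (2 * 3 + 5) / 6) * log(0.5)
  got <- bartlett_sphericity(R3, n)
  expect_equal(got$chi2, want, tolerance = 1e-12)
  expect_equal(got$df, 3)
  expect_error(bartlett_sphericity(matrix(c(1, 1, 1, 1), 2), 10),
               "determinant")
  expect_error(bartlett_sphericity(diag(5), 4))
})

test_that("PAF+Promax recovers a planted two-factor block structure", {
  set.seed(7)
  n <- 2000; p <- 20
  Ltrue <- matrix(0, p, 2)
  Ltrue[1:10, 1] <- 0.8
  Ltrue[11:20, 2] <- 0.8
  FF <- matrix(rnorm(n * 2), n, 2)
  x <- FF %*% t(Ltrue) +
    matrix(rnorm(n * p), n, p) %*% diag(sqrt(1 - rowSums(Ltrue^2)))
  fit <- paf_promax(x)
  expect_equal(fit$n_factors, 2)           # Kaiser retains exactly 2
  expect_true(fit$converged)
  expect_true(tucker_congruence(fit$loadings, Ltrue) > 0.95)
  expect_true(all(fit$communalities >= 0 & fit$communalities <= 1))
  expect_equal(fit$bartlett_df, p * (p - 1) / 2)
})

test_that("single-factor solutions skip rotation and match the eigen sum", {
  set.seed(8)
  n <- 1000; p <- 8
  f <- rnorm(n)
  x <- sapply(1:p, function(i) 0.7 * f + sqrt(1 - 0.49) * rnorm(n))
  fit <- paf_promax(x)
  expect_equal(fit$n_factors, 1)
  expect_identical(dim(fit$phi), c(1L, 1L))
  # sum of squared loadings equals the top eigenvalue of the reduced matrix
  R <- cor(x)
  diag(R) <- fit$communalities
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values[1]
  expect_equal(sum(fit$loadings^2), ev, tolerance = 1e-6)
  # all loadings share one sign
  expect_true(all(fit$loadings > 0) || all(fit$loadings < 0))
})

test_that("default synthetic cohorts separate hearing and non-hearing blocks", {
  bank <- hc_test_bank
  hr <- items_in_group(bank, "hearing_related")
  seeds <- 1:5
  pass <- vapply(seeds, function(s) {
    cfg <- generator_config(
      seed = s,
      subgroup_sizes = c(NH = 540, U_MI = 437, U_MO = 316, U_MS = 56,
                         A_MI = 84, A_MO = 344, A_MS = 223),
      country_mix = c(Germany = 828, Egypt = 502, USA = 670))
    g <- generate_cohort(cfg, bank)
    m <- hearcommand:::coded_grades(g$cohort, bank)[,
      items_in_group(bank, "all_scored"), drop = FALSE]
    fit <- paf_promax(m, n_factors = 7)
    primary <- apply(abs(fit$loadings), 1, which.max)
    is_hr <- rownames(fit$loadings) %in% hr
    # a factor's type is the majority type of its items; an item agrees
    # when its primary factor has its own type
    agree <- vapply(seq_along(primary), function(i) {
      mine <- primary[i]
      mates <- is_hr[primary == mine]
      (mean(mates) >= 0.5) == is_hr[i]
    }, TRUE)
    mean(agree) >= 0.9
  }, TRUE)
  expect_true(mean(pass) >= 0.8)
})
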