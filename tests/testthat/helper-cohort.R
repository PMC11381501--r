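# Shared fixtures: the canonical bank is loaded once; small cohorts are
# built in code.

hc_test_bank <- load_item_bank()

# cohort where every respondent gives the same graded answer everywhere
# (gating then blanks the closed blocks)
uniform_cohort <- function(n, grade = "1", n_aided = 0, n_speech = 0,
                           bank = hc_test_bank, pta = NULL) {
  ids <- sprintf("R%03d", seq_len(n))
  resp <- matrix(as.character(grade), n, 90,
                 dimnames = list(ids, bank$items$id))
  demo <- data.frame(
    id = ids,
    hearing_aid_user = seq_len(n) <= n_aided,
    speech_impaired = seq_len(n) <= n_speech,
    stringsAsFactors = FALSE)
  if (!is.null(pta)) demo$pta_better <- pta
  suppressWarnings(new_cohort(demo, resp, bank))
}

# brute-force Mann-Whitney oracle: full enumeration of label assignments
brute_force_mw <- function(a, b) {
  n1 <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(pooled), n1)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]))
  u1 <- w_obs - n1 * (n1 + 1) / 2
  list(
    u = min(u1, n1 * length(b) - u1),
    p = min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs))))
}

# correlated normal data with exchangeable correlation rho
compound_symmetric <- function(n, k, rho, seed = 1) {
  set.seed(seed)
  S <- matrix(rho, k, k)
  diag(S) <- 1
  matrix(rnorm(n * k), n, k) %*% chol(S)
}

# Tucker congruence between loading matrices, maximized over column
# permutation and sign
tucker_congruence <- function(L, Ltrue) {
  stopifnot(ncol(L) == ncol(Ltrue))
  k <- ncol(L)
  perms <- if (k == 2L) list(1:2, 2:1) else
    combinat_perms(k)
  best <- -Inf
  for (p in perms) {
    cc <- vapply(seq_len(k), function(j) {
      x <- L[, p[j]]; y <- Ltrue[, j]
      abs(sum(x * y)) / sqrt(sum(x^2) * sum(y^2))
    }, 0)
    best <- max(best, min(cc))
  }
  best
}

combinat_perms <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    for (rest in combinat_perms(k - 1L)) {
      out[[length(out) + 1L]] <- c(i, setdiff(seq_len(k), i)[rest])
    }
  }
  out
}
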