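#' @title Psychometric validation battery
#' @description
#' The validation statistics used for the instrument: per-item
#' descriptives with floor/ceiling effects (15% cutoff), Cronbach's alpha
#' with listwise deletion, the Mann-Whitney U test (exact by enumeration
#' for small groups, tie- and continuity-corrected normal approximation
#' otherwise), the Kaiser-Meyer-Olkin measure of sampling adequacy,
#' Bartlett's test of sphericity, and exploratory factor analysis by
#' principal-axis factoring with Promax rotation and Kaiser
#' (eigenvalue-above-unity) retention.
#' @name psychometrics
NULL

#' Per-item descriptive statistics and floor/ceiling effects
#'
#' Summary statistics are computed over graded responses only; the
#' floor/ceiling proportions use all respondents in the denominator, and
#' an effect is present when strictly more than `cutoff` of respondents
#' chose the extreme grade.
#'
#' @param cohort an `hc_cohort` (gating applied).
#' @param bank item bank.
#' @param cutoff floor/ceiling proportion cutoff (default 0.15).
#' @return Data frame, one row per item: `item_id`, `n_graded`,
#'   `n_non_gradable`, `min`, `max`, `mean`, `sd`, `median`,
#'   `prop_floor`, `prop_ceiling`, `floor_present`, `ceiling_present`.
#' @export
describe_items <- function(cohort, bank, cutoff = 0.15) {
  stopifnot(inherits(cohort, "hc_cohort"), inherits(bank, "hc_bank"))
  g <- response_grades(cohort)
  n <- nrow(g)
  if (n == 0L) stop("empty cohort")
  stat <- function(f) apply(g, 2, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else f(v)
  })
  n_graded <- colSums(!is.na(g))
  data.frame(
    item_id = colnames(g),
    n_graded = n_graded,
    n_non_gradable = n - n_graded,
    min = stat(min), max = stat(max), mean = stat(mean),
    sd = apply(g, 2, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2L) NA_real_ else stats::sd(v)
    }),
    median = stat(stats::median),
    prop_floor = colMeans(g == 0, na.rm = TRUE) * n_graded / n,
    prop_ceiling = colMeans(g == 4, na.rm = TRUE) * n_graded / n,
    stringsAsFactors = FALSE,
    row.names = NULL
  ) -> out
  # colMeans na.rm divides by n_graded; rescale to the all-respondent share
  out$prop_floor[n_graded == 0L] <- 0
  out$prop_ceiling[n_graded == 0L] <- 0
  out$floor_present <- out$prop_floor > cutoff
  out$ceiling_present <- out$prop_ceiling > cutoff
  out$undefined <- n_graded == 0L
  out
}

#' Cronbach's alpha
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance(total))`,
#' computed after listwise deletion over the selected items.  When given a
#' cohort, grades are coded first (facilitator items mirrored) so that all
#' items point in the hardship direction.
#'
#' @param x an `hc_cohort` or a numeric respondent-by-item matrix.
#' @param items item ids to include (cohort input; default: the 78 scored
#'   items).
#' @param bank item bank (required for cohort input).
#' @return A `hc_alpha` list: `alpha`, `n_items`,
#'   `n_complete_respondents`, `item_total_correlations` (item vs rest).
#' @export
cronbach_alpha <- function(x, items = NULL, bank = NULL) {
  if (inherits(x, "hc_cohort")) {
    stopifnot(inherits(bank, "hc_bank"))
    if (is.null(items)) items <- items_in_group(bank, "all_scored")
    m <- coded_grades(x, bank)[, items, drop = FALSE]
  } else {
    m <- as.matrix(x)
  }
  k <- ncol(m)
  if (k < 2L) stop("need at least 2 items")
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 2L) stop("fewer than 2 complete respondents after listwise deletion")
  total <- rowSums(m)
  vt <- stats::var(total)
  if (vt == 0) stop("zero total-score variance")
  alpha <- k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / vt)
  itc <- vapply(seq_len(k), function(j) {
    rest <- total - m[, j]
    if (stats::sd(m[, j]) == 0 || stats::sd(rest) == 0) NA_real_
    else stats::cor(m[, j], rest)
  }, 0)
  names(itc) <- colnames(m)
  structure(list(alpha = alpha, n_items = k,
                 n_complete_respondents = nrow(m),
                 item_total_correlations = itc),
            class = "hc_alpha")
}

#' @export
print.hc_alpha <- function(x, ...) {
  cat(sprintf("Cronbach's alpha = %.3f (%d items, %d complete respondents)\n",
              x$alpha, x$n_items, x$n_complete_respondents))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' U is computed from rank sums with midranks for ties.  When
#' `n1 * n2 <= exact_limit` the two-sided p-value is exact, from the full
#' permutation distribution of the rank sum (a shift-algorithm count over
#' doubled midranks, valid under ties); otherwise a normal approximation
#' with tie correction and continuity correction is used.  The reported
#' statistic is `min(U1, U2)`.
#'
#' @param a,b numeric score vectors for the two groups.
#' @param exact_limit exact-enumeration switch (default 400 on
#'   `n1 * n2`).
#' @return A `hc_utest` list: `statistic` (min U), `u1`, `z_value`,
#'   `p_value`, `n1`, `n2`, `method`.
#' @export
mann_whitney <- function(a, b, exact_limit = 400) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty")
  pooled <- c(a, b)
  r <- rank(pooled)
  w1 <- sum(r[seq_len(n1)])
  u1 <- w1 - n1 * (n1 + 1) / 2
  u <- min(u1, n1 * n2 - u1)
  n <- n1 + n2
  ties <- table(pooled)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  mu <- n1 * n2 / 2
  z <- if (sigma2 > 0) {
    (u1 - mu - sign(u1 - mu) * 0.5) / sqrt(sigma2)
  } else 0
  if (sigma2 == 0) {
    p <- 1
    method <- "degenerate (all values tied)"
  } else if (n1 * n2 <= exact_limit) {
    p <- exact_ranksum_p(r, n1)
    method <- "exact permutation distribution"
  } else {
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation with tie and continuity correction"
  }
  structure(list(statistic = u, u1 = u1, z_value = z,
                 p_value = min(1, p), n1 = n1, n2 = n2, method = method),
            class = "hc_utest")
}

# Exact two-sided p for the rank sum of the first group:
# counts, over all C(n, n1) label assignments, subsets by their (doubled,
# hence integer) midrank sum; p = min(1, 2 * min(lower tail, upper tail)).
exact_ranksum_p <- function(r, n1) {
  s <- as.integer(round(2 * r))
  n <- length(s)
  maxsum <- sum(sort(s, decreasing = TRUE)[seq_len(n1)])
  # f[k+1, t+1] = number of size-k subsets with doubled-rank sum t
  f <- matrix(0, n1 + 1L, maxsum + 1L)
  f[1L, 1L] <- 1
  for (x in s) {
    kmax <- n1
    for (k in kmax:1) {
      idx <- seq_len(maxsum + 1L - x)
      f[k + 1L, idx + x] <- f[k + 1L, idx + x] + f[k, idx]
    }
  }
  dist <- f[n1 + 1L, ]
  total <- sum(dist)
  obs <- sum(s[seq_len(n1)])
  lower <- sum(dist[seq_len(obs + 1L)]) / total
  upper <- sum(dist[(obs + 1L):(maxsum + 1L)]) / total
  min(1, 2 * min(lower, upper))
}

#' @export
print.hc_utest <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n1 = %d, n2 = %d), z = %.3f, p = %.4g\n",
              x$statistic, x$n1, x$n2, x$z_value, x$p_value))
  cat("  ", x$method, "\n", sep = "")
  invisible(x)
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' `KMO = sum(r^2) / (sum(r^2) + sum(q^2))` over the off-diagonal entries,
#' where `q` are the anti-image partial correlations obtained from the
#' inverse correlation matrix.
#'
#' @param R correlation matrix (symmetric, positive definite).
#' @return List with `kmo` (overall) and `msa` (per-variable measures).
#' @export
kmo <- function(R) {
  R <- as.matrix(R)
  p <- ncol(R)
  stopifnot(p >= 2L, isSymmetric(unname(R), tol = 1e-8))
  S <- tryCatch(solve(R), error = function(e) {
    stop("correlation matrix is singular; regularize (e.g. smooth to ",
         "positive definite or drop collinear items) before computing KMO")
  })
  d <- 1 / sqrt(diag(S))
  Q <- -S * tcrossprod(d)      # anti-image partial correlations
  diag(Q) <- 0
  R0 <- R
  diag(R0) <- 0
  r2 <- sum(R0^2)
  q2 <- sum(Q^2)
  msa <- colSums(R0^2) / (colSums(R0^2) + colSums(Q^2))
  list(kmo = r2 / (r2 + q2), msa = msa)
}

#' Bartlett's test of sphericity
#'
#' Tests whether a correlation matrix is the identity:
#' `X2 = -(n - 1 - (2p + 5)/6) * log(det(R))` with `p(p-1)/2` degrees of
#' freedom.
#'
#' @param R correlation matrix.
#' @param n sample size used to estimate `R` (must exceed `p`).
#' @return List with `chi2`, `df`, `p_value`.
#' @export
bartlett_sphericity <- function(R, n) {
  R <- as.matrix(R)
  p <- ncol(R)
  stopifnot(n > p)
  dt <- det(R)
  if (!is.finite(dt) || dt <= 0) stop("non-positive determinant")
  chi2 <- -(n - 1 - (2 * p + 5) / 6) * log(dt)
  df <- p * (p - 1) / 2
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Exploratory factor analysis: principal-axis factoring with Promax
#'
#' Extraction iterates communality estimates (initial values: squared
#' multiple correlations) on the reduced correlation matrix until the
#' largest communality change is below `tol` or `max_iter` is reached.
#' The number of factors follows the Kaiser rule (eigenvalues of the
#' unreduced correlation matrix above 1) unless `n_factors` is fixed.
#' With more than one factor the solution is varimax-rotated (Kaiser
#' normalization) and then obliquely rotated by Promax with power
#' `kappa`.  Heywood cases (communalities exceeding 1) are clipped and
#' flagged.
#'
#' @param x respondent-by-item numeric matrix (non-gradable entries `NA`;
#'   Pearson correlations with pairwise-complete deletion), or a
#'   correlation matrix with `n_obs` supplied.
#' @param n_factors `NULL` for Kaiser retention, or a fixed count.
#' @param kappa Promax power (default 4).
#' @param max_iter,tol communality-iteration controls.
#' @param n_obs sample size when `x` is already a correlation matrix.
#' @return An `hc_efa` object: `n_items`, `n_factors`, `eigenvalues`
#'   (unreduced correlation matrix), `loadings` (Promax pattern matrix),
#'   `phi` (factor correlations), `communalities`,
#'   `variance_explained`, `kmo`, `bartlett_chi2`, `bartlett_df`,
#'   `bartlett_p`, `n_iterations`, `converged`, `heywood`.
#' @export
paf_promax <- function(x, n_factors = NULL, kappa = 4,
                       max_iter = 100L, tol = 1e-3, n_obs = NULL) {
  x <- as.matrix(x)
  is_cor <- !is.null(n_obs) && nrow(x) == ncol(x) &&
    isSymmetric(unname(x), tol = 1e-8) && all(abs(diag(x) - 1) < 1e-8)
  if (is_cor) {
    R <- x
    n <- n_obs
  } else {
    if (nrow(x) <= ncol(x)) {
      warning("fewer respondents than items; factor solution is unstable",
              call. = FALSE)
    }
    R <- stats::cor(x, use = "pairwise.complete.obs")
    if (anyNA(R)) stop("correlation matrix has missing entries ",
                       "(an item pair with no joint observations?)")
    n <- nrow(x)
  }
  p <- ncol(R)
  R <- smooth_to_pd(R)
  eig_full <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  k <- if (is.null(n_factors)) sum(eig_full > 1) else as.integer(n_factors)
  if (k < 1L) stop("no factor retained")
  adequacy <- kmo(R)
  bart <- bartlett_sphericity(R, n)

  # principal-axis extraction
  h2 <- 1 - 1 / diag(solve(R))       # squared multiple correlations
  heywood <- FALSE
  converged <- FALSE
  extract <- function(h2) {
    Rr <- R
    diag(Rr) <- h2
    e <- eigen(Rr, symmetric = TRUE)
    vals <- pmax(e$values[seq_len(k)], 0)
    e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(vals), k)
  }
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    h2_new <- rowSums(extract(h2)^2)
    if (any(h2_new > 1)) {
      heywood <- TRUE
      h2_new <- pmin(h2_new, 1)
    }
    delta <- max(abs(h2_new - h2))
    h2 <- h2_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  # final extraction at the converged communalities: the returned loadings
  # are exactly the principal-axis solution of the reduced matrix whose
  # diagonal holds the returned communalities
  L <- extract(h2)
  rownames(L) <- colnames(R)
  colnames(L) <- paste0("F", seq_len(k))

  if (k == 1L) {
    pattern <- L
    phi <- matrix(1, 1, 1)
  } else {
    vm <- stats::varimax(L, normalize = TRUE)
    A <- vm$loadings[, , drop = TRUE]
    A <- matrix(A, nrow = p, ncol = k, dimnames = dimnames(L))
    pr <- promax_rotate(A, kappa)
    pattern <- pr$pattern
    phi <- pr$phi
  }
  structure(list(
    n_items = p, n_factors = k, eigenvalues = eig_full,
    loadings = pattern, phi = phi, communalities = stats::setNames(h2, colnames(R)),
    variance_explained = sum(h2) / p,
    kmo = adequacy$kmo, bartlett_chi2 = bart$chi2, bartlett_df = bart$df,
    bartlett_p = bart$p_value, n_iterations = iter,
    converged = converged, heywood = heywood), class = "hc_efa")
}

# Promax: least-squares rotation of a varimax solution towards the
# element-wise power-kappa target; columns scaled so the implied factor
# correlation matrix phi has unit diagonal.
promax_rotate <- function(A, kappa = 4) {
  Q <- A * abs(A)^(kappa - 1)
  U <- solve(crossprod(A)) %*% crossprod(A, Q)
  d <- diag(solve(crossprod(U)))
  U <- U %*% diag(sqrt(d))
  pattern <- A %*% U
  phi <- solve(crossprod(U))
  dimnames(pattern) <- dimnames(A)
  dimnames(phi) <- list(colnames(A), colnames(A))
  list(pattern = pattern, phi = phi)
}

# clip negative eigenvalues and rescale to unit diagonal
smooth_to_pd <- function(R, eps = 1e-8) {
  e <- eigen(R, symmetric = TRUE)
  if (all(e$values > eps)) return(R)
  v <- pmax(e$values, eps)
  S <- e$vectors %*% diag(v) %*% t(e$vectors)
  d <- 1 / sqrt(diag(S))
  S <- S * tcrossprod(d)
  dimnames(S) <- dimnames(R)
  S
}

#' @export
print.hc_efa <- function(x, suppress = 0.30, ...) {
  cat(sprintf(
    "Principal-axis factoring, Promax rotation: %d items, %d factors\n",
    x$n_items, x$n_factors))
  cat(sprintf("  KMO = %.3f; Bartlett X2(df = %d) = %.1f, p = %.3g\n",
              x$kmo, x$bartlett_df, x$bartlett_chi2, x$bartlett_p))
  cat(sprintf("  variance explained = %.1f%%; %d iterations%s%s\n",
              100 * x$variance_explained, x$n_iterations,
              if (x$converged) "" else " (NOT converged)",
              if (x$heywood) "; Heywood case clipped" else ""))
  L <- x$loadings
  L[abs(L) < suppress] <- NA
  print(round(L, 3), na.print = "")
  invisible(x)
}
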