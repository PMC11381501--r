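---
title: "Methods: scoring and validating an ICF-based hearing questionnaire"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring and validating an ICF-based hearing questionnaire}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hearcommand)
```

## The instrument and its structure

The HEAR-COMMAND tool is a 90-item patient-reported outcome questionnaire
built on the WHO International Classification of Functioning, Disability
and Health (ICF) Core Sets for Hearing Loss. Items `H.1`–`H.48` probe body
functions (BF), `H.49`–`H.74` activities and participation (AP), and
`H.75`–`H.90` environmental factors (EF). Each item is answered on a
five-point ordinal scale — 0 (no problem) to 4 (profound/complete) — or
with a non-gradable category: *I don't know*, *Not applicable*, *Not
required* (set by gating), or left blank.

Two filter questions gate dependent blocks: respondents without speech
impairment skip the voice-and-speech-production block `H.42`–`H.48`, and
respondents who do not use a hearing aid skip the aid-benefit block
`H.87`–`H.90`. `apply_gating()` records both blocks as *Not required* for
gated-off respondents, overwriting (with a warning) any stray grades.

Exploratory factor analysis of the 78 always-administered items grouped
them into seven labelled constructs: A (auditory processing, 20 items), B
(interpersonal interaction and infrastructure access, 18), C (sound
quality compatibility, 4), D (social support and infrastructure, 6), E
(listening and communication, 13), F (other sensory integration, 9) and G
(cognitive functioning, 8). Constructs A, C and E form the 37
*hearing-related* items; B, D, F, G the 41 *non-hearing-related* items;
removing the five items of A whose target sounds are non-speech
(`H.25`, `H.26`, `H.27`, `H.29`, `H.31`) leaves the 32 *speech-perception*
items. These memberships, including the handful of cross-loading items
placed with their largest loading, are frozen in the canonical JSON
configuration shipped with the package and validated — never recomputed —
at load time. One known discrepancy in the source material (an item table
reporting 36/42 instead of 37/41) is resolved in favour of 37/41, which
the published raw maxima \(148 = 37 \times 4\) and \(164 = 41 \times 4\)
confirm.

## Outcome scores

Environmental facilitators (`H.75`–`H.80`) are worded so that 4 means
maximal *support*; before aggregation their grades are mirrored,
\(g \mapsto 4 - g\), so that 4 uniformly means maximal hardship. The
barriers `H.81`–`H.86` are not mirrored, and `H.87`–`H.90`, although
facilitators, sit outside every score group.

A raw score is the sum of coded grades over a group's graded items
(maxima 148, 164, 128). Normalization maps it to 0–10:

* **published** mode multiplies by the printed coefficients 0.067, 0.061
  and 0.0782. 0.067 is a *truncation* of \(10/148 = 0.06757\), not a
  rounding; and \(164 \times 0.061 = 10.004\) slightly overshoots, so
  published-mode scores are capped at 10 to preserve the scale invariant.
  This mode reproduces printed numbers exactly and requires full
  coverage.
* **exact** mode multiplies by \(10/(4n)\) for a group of \(n\) items
  (full coverage required).
* **prorated** mode — the operational default — computes
  \(10 \cdot \mathrm{raw}/(4 \cdot n_\mathrm{graded})\), preserving the
  0–10 reading when some items are non-gradable. A score is flagged
  invalid below a minimum coverage, default 0.80. The source material
  does not state how partially answered questionnaires were handled;
  proration without imputation is this package's choice, and at full
  coverage it coincides with exact mode.

## Classification

The better-ear pure-tone average (mean threshold at 0.5/1/2/4 kHz)
classifies hearing by the Global Burden of Disease bands, half-open by
convention since the printed ranges overlap at their ends: normal
\([\,{<}20)\), mild \([20, 35)\), moderate \([35, 50)\), moderately
severe \([50, 65)\) dB HL. The validation population excluded
severe-to-profound loss, so \(\mathrm{PTA} \ge 65\) is reported as out of
the validated range rather than forced into a class.

Disability degrees derive from the population mean \(M\) and standard
deviation \(SD\) of a normalized score: No \([0, M{-}SD)\), Mild
\([M{-}SD, M)\), Moderate \([M, M{+}SD)\), Severe \([M{+}SD, \cdot)\).
The shipped reference cut points — speech \((M, SD) = (2.4, 1.7)\),
hearing \((2.5, 1.8)\), non-hearing \((1.8, 1.3)\) — are
population-dependent; `derive_thresholds()` recomputes them for any
cohort using the sample (\(n-1\)) standard deviation (the default of the
statistics package in which they were originally derived; whether a
population SD was used instead is not stated).

## Validation statistics

All of these are implemented in the package rather than delegated,
because they *are* the methodological content:

* **Descriptives and floor/ceiling effects.** Statistics are computed
  over graded responses; the floor (ceiling) effect is present when
  strictly more than 15% of *all* respondents chose grade 0 (grade 4).
* **Cronbach's alpha**,
  \(\alpha = \frac{k}{k-1}\bigl(1 - \sum_i \sigma_i^2 / \sigma_T^2\bigr)\),
  with listwise deletion, on coded (mirrored) grades. Note the
  covariance-based alpha is invariant to a common positive rescaling and
  per-item shifts, but *not* to item-specific slopes.
* **Mann–Whitney U** with midranks. For \(n_1 n_2 \le 400\) the
  two-sided p-value is exact: the permutation distribution of the rank
  sum is obtained by a shift-algorithm count over doubled midranks,
  which is identical to full enumeration (and is verified against brute
  force in the tests) while remaining feasible at \(n_1 = n_2 = 20\),
  where literal enumeration would need \(\binom{40}{20} \approx 10^{11}\)
  subsets. Larger samples use the normal approximation with tie and
  continuity corrections.
* **KMO** \(= \sum r^2 / (\sum r^2 + \sum q^2)\) over off-diagonals,
  with anti-image partial correlations \(q\) from the inverse
  correlation matrix; singular matrices produce an error advising
  regularization.
* **Bartlett's sphericity**
  \(X^2 = -(n - 1 - (2p+5)/6)\,\ln\det R\), \(df = p(p-1)/2\)
  (so \(df = 3003\) at \(p = 78\)).
* **Principal-axis factoring** iterates communalities from squared
  multiple correlations (max 100 iterations, convergence when the
  largest change is below \(10^{-3}\)); Heywood cases are clipped and
  flagged. After convergence one final extraction is performed at the
  converged communalities, so the returned loadings are exactly the
  principal-axis solution of the reduced matrix whose diagonal holds the
  returned communalities — this makes the eigenvalue/loading-sum
  identity hold to numerical precision. Retention follows the Kaiser
  rule on the *unreduced* correlation matrix. With two or more factors
  the solution is varimax-rotated (Kaiser normalization) and then
  target-rotated by Promax with power \(\kappa = 4\) (configurable).
  Correlations are Pearson on the 0–4 grades, pairwise complete;
  indefinite matrices are smoothed by eigenvalue clipping. Polychoric
  correlations and confirmatory models are out of scope.

## The synthetic cohort generator

No respondent-level data are deposited, so every end-to-end test runs on
synthetic cohorts whose *structure* — not whose conclusions — mimics the
validation population:

* Subgroups: normal hearing 58; unaided mild/moderate/moderately severe
  47/34/6; aided 9/37/24 (total 215, 70 aided); countries 89/54/72;
  11 speech-impaired respondents (1 normal hearing, 7 unaided, 3 aided);
  better-ear PTA uniform within each class band, worse ear offset by a
  folded normal with mean 6.1 and SD 5.9 dB.
* A seven-construct latent model: constructs are multivariate normal
  with exchangeable correlation 0.5; hearing-loss severity shifts the
  hearing-related constructs (A, C, E) by 0.8/1.2/1.6 latent SD for
  mild/moderate/moderately-severe and the remaining constructs by
  0.65/0.80/1.00. Item latent values are
  \(\lambda_j F_{c(j)} + \sqrt{1-\lambda_j^2}\,\varepsilon\)
  (unit variance; default \(\lambda_j\) cycle through 0.5–0.9), graded
  through four ordinal thresholds. The severity shifts were calibrated
  once, by simulation, so that default-cohort summaries land near the
  published population values (measured on seeds 1–6: hearing score mean
  ≈ 2.56, non-hearing ≈ 1.85 on the 0–10 scale, versus reference means
  2.5 and 1.8), then frozen before the acceptance suite was written.
* Facilitator items store the reflected grade \(4-g\), producing the
  high raw means observed for support items; the aid-benefit block gets
  raised thresholds so aided users' raw means land near 3.0–3.4.
  Barrier items `H.81`–`H.86` get lowered thresholds (raw means near 2).
* Non-gradable responses are injected at a mean 4.2% item rate (with
  per-item jitter), with elevated rates on the seven
  "not applicable"-prone items; only two of those seven rates are stated
  in the source (29% and 21%); the rest are synthetic values inside the
  stated 14.9–29.8% range. Crucially, injection is *clustered within
  respondents* through a gamma(0.3) propensity multiplying the item
  rates: marginal item rates are unchanged, but most respondents answer
  everything while a few skip many items. Independent injection at the
  same marginal rate would leave roughly two listwise-complete
  respondents out of 215, making the published 78-item alpha
  uncomputable — whereas the original study plainly computed it.

What a green test does *not* establish: the generator makes no claim
about real response distributions per item (only summary-level
statements were available), carries no country or age effects, and its
factor structure is planted — recovery tests demonstrate the estimator
works, not that the instrument has this structure in any population.

## Numerical and design notes

* Scores are reported to two decimals in outputs; full precision is kept
  internally.
* Boundary scores fall upward: a score exactly at \(M-SD\) is Mild, at
  \(M\) Moderate, at \(M+SD\) Severe.
* Exact-vs-approximate Mann–Whitney switches at \(n_1 n_2 = 400\);
  a degenerate comparison (all values tied) reports \(p = 1\).
* The reliability table reports the six published item combinations
  (40/26/37/41/78/82 items); the 82-item combination is computed on
  hearing-aid users only, since the aid-benefit block is non-gradable
  for everyone else. Combinations that cannot produce an alpha (fewer
  than two complete respondents, zero variance) are reported as `NA`
  with a note rather than an error.
* Pipeline runs write a manifest (input digests, seed, package version);
  reruns with identical inputs and seed produce byte-identical outputs
  apart from the manifest's timestamp.
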