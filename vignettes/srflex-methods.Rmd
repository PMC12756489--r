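---
title: "Methods: lexicon-based suicide-risk modelling of crisis chats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lexicon-based suicide-risk modelling of crisis chats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

srflex implements a transparent pipeline for studying how suicide risk (SR)
is expressed in text-based crisis-helpline conversations: a phrase lexicon of
psychological constructs is matched against help-seeker messages, the
per-category match counts feed multivariable logistic regressions, and the
resulting odds ratios — overall, stratified by gender or age group, and traced
across the course of the conversation — are the interpretable output. A
synthetic corpus generator with a fully known ground truth stands in for
confidential helpline data and makes every stage of the pipeline testable.

## The model

Each chat session $i$ carries a binary SR label $y_i$ (explicit suicidal
ideation expressed in the chat) and a feature vector
$x_i = (x_{i1}, \dots, x_{iK})$, where $x_{ij}$ counts the non-overlapping
matches of lexicon category $j$ (hopelessness, loneliness, previous suicide
attempt, ...) in the cleaned help-seeker text. The model is an ordinary
multivariable logistic regression with intercept,

$$\operatorname{logit} \Pr(y_i = 1 \mid x_i) = \beta_0 + \textstyle\sum_j \beta_j x_{ij},$$

so $e^{\beta_j}$ is the multiplicative change in SR odds per additional
mention of construct $j$, holding the other constructs fixed. Wald 95%
confidence intervals are computed on the log-odds scale and exponentiated;
significance is the two-sided Wald test at $\alpha = 0.05$, which is exactly
equivalent to the CI excluding 1. Profile-likelihood intervals are not
implemented: at the sample sizes this design targets (thousands of sessions,
modest coefficients) the quadratic approximation is accurate, and Wald
intervals keep the OR table self-consistent. No multiple-testing correction
is applied by default (per-predictor reporting is the field convention here);
`p_adjust = "BH"` is available.

Fitting is iteratively reweighted least squares via `stats::glm.fit`
(relative deviance change below 1e-10, at most 100 iterations), with the
covariance taken from the inverse observed information. Quasi-complete
separation — diverging coefficients with fitted probabilities pinned to 0 or
1 — is detected heuristically (boundary fitted values together with a slope
exceeding 8 on the log-odds scale or a standard error above 20) and flagged;
`effects_table()` refuses a separated fit rather than reporting meaningless
intervals. Non-convergence without separation is an error, never a silent
result.

## The matcher

Matching is deliberately rigid: no stemming, no lemmatization, no fuzzy or
embedding-based matching. A phrase is a token sequence; the compiled matcher

* folds case and applies Unicode NFC normalization,
* treats any run of non-letter/non-digit characters between tokens as a
  single separator (so "no,  hope" matches "no hope"),
* anchors both phrase ends at word boundaries, defined as transitions
  between letter/digit characters and everything else — a language-neutral
  definition that behaves identically for Hebrew and Latin scripts
  ("hopeless" never matches inside "hopelessness").

Counting selects non-overlapping matches per category from the pooled
candidates of all the category's phrases, scanning left to right, preferring
the leftmost start and, at equal starts, the longest match. This is the
standard deterministic lexicon-matcher semantics; frequency (not binary
presence) is counted because the odds ratios are per-mention effects, though
a binary-presence switch exists (`presence = TRUE`). Categories are counted
independently, so one span may legitimately count in two categories —
constructs are separate theoretical entities. `explain_matches()` returns
the exact character spans behind every count, which is what makes the
pipeline auditable: any session's score can be traced to the phrases that
produced it.

The batch matcher uses a vectorised candidate scan with a provably
equivalent fallback: whenever a text's pooled candidates overlap or a
leading word boundary is in doubt, the exact lazy enumeration takes over.
The test suite asserts equivalence against a brute-force oracle (anchored
matching attempted at every character position, greedy selection from the
full candidate list) on a thousand adversarial random instances.

One caveat worth stating: with pathological lexicons in which one long
phrase extends a shorter phrase of the same category, adding text to a
prefix can merge two short matches into one long one, so counts are not
formally monotone under text growth. With realistic lexicons (and with the
generator's corpora, where planted phrases are always separated by filler)
prefix counts are exactly monotone, and the tests assert this.

## Sessions, cleaning and prefix slicing

Cleaning removes URLs, markup tags and control characters, collapses
whitespace, trims, case-folds and NFC-normalises; it is idempotent. Only
help-seeker messages are matched — counselor turns are excluded so that
intervention language (a counselor asking "are you feeling hopeless?")
cannot leak into the risk features.

Temporal analysis slices each session at progress fractions
$f \in \{0.2, 0.4, 0.6, 0.8, 1.0\}$. The slicing unit is the cumulative
cleaned character count of help-seeker messages, at whole-message
granularity: the slice is the shortest message prefix whose cumulative
help-seeker characters reach $f$ times the session total, with interleaved
counselor messages retained. Character count was chosen over message count
because message lengths vary enormously in chat data and risk language lives
in the amount of text produced, not the number of messages; a message-count
alternative is exposed (`unit = "messages"`). Prefixes are nested by
construction, and the fraction-1.0 slice is the identity.

## Stratified and temporal fits

`fit_by_stratum()` fits one model per stratum: gender strata are
all/female/male (sessions with unknown gender stay in "all" and drop from
the gender-specific models, matching the sample-accounting discipline of the
reference corpus table), age strata are the four developmental bins
10–17, 18–20, 21–40, 41+. Every stratified result carries its n and SR
prevalence. `temporal_trajectories()` refits the full multivariable model on
features rebuilt at each fraction — a repeated cross-sectional design, not a
longitudinal model — so the fraction-1.0 trajectory point coincides exactly
with the static fit. All categories are always fitted and reported at every
fraction; readers can filter to significant ones. No cross-stratum
coefficient tests are part of the core reporting (stratified estimates are
within-group associations); a clearly-labelled Wald contrast utility
(`wald_contrast()`) is provided as an extension.

## Evaluation and agreement

`evaluate_holdout()` splits sessions into train/test (stratified by outcome,
deterministic under a seed; the split protocol and the 0.5 classification
threshold are package choices, reported alongside the metrics), fits on the
training rows and reports precision, recall, $F_1$, $F_2$ and ROC–AUC.
$F_\beta = (1+\beta^2) P R / (\beta^2 P + R)$; zero denominators yield 0
with a warning. AUC is the rank-based (Mann–Whitney) statistic with midranks
for ties, which equals trapezoidal integration of the empirical ROC curve;
the tests verify both that identity and agreement with pROC.

Inter-rater agreement offers Cohen's $\kappa$ for two raters; for more than
two raters the package defaults to the mean of pairwise Cohen kappas
(flagged in the result) with Fleiss' $\kappa$ as the alternative, since a
single reported kappa from three reviewers does not determine the reduction
used. Degenerate tables with expected agreement 1 are errors, not NaNs.

Calibration uses the Hosmer–Lemeshow test: sessions sorted by predicted
probability, ten near-equal bins (tied predictions stay together; the
degrees of freedom follow the realised bin count minus 2),
$\chi^2 = \sum (O - E)^2 / E$ over bins and both outcome classes. A bin with
zero expected count is an error advising fewer groups.

## The synthetic generator

Real crisis chats are confidential, so the generator produces corpora whose
every relevant property is known:

* **Demographics.** Each session draws a (gender, age) cell from
  probabilities proportional to the reference subgroup table
  (`crisis_sample_table()`: 17,564 sessions; 12,074 female / 5,343 male /
  147 unknown; four age bins plus unknown), treating the two margins as
  independent.
* **Counts.** For category $j$ and stage $s \in 1..5$, the planted count is
  Poisson with mean $\lambda_{js}$. The default is stage-uniform
  $\lambda_{js} = 0.3$ (1.5 expected mentions per category per chat): a
  realistic per-construct mention intensity for short crisis chats, and
  enough count variance that the weakest planted effect (loneliness in
  women, OR 1.07) is detectable at the reference sample size with roughly
  90% power — the package's own power choice, made once, not a fitted
  value. Depression and thwarted belongingness get a late-weighted profile
  (relative stage weights 0.4/0.7/1.0/1.3/1.6 with the same per-chat total),
  mirroring constructs that surface late in conversations.
* **Labels.** $y_i \sim \text{Bernoulli}(\text{logit}^{-1}(\beta_{0,\text{cell}} +
  \beta_{\text{gender}} \cdot x_i^{\text{total}}))$ with true per-mention
  odds ratios set to the reported gender-specific point estimates (previous
  attempt 1.29/1.26 for women/men, hopelessness 1.24/1.29, self-harm
  1.17/1.16, thwarted belongingness 1.06/1.12, loneliness 1.07 in women
  only, depression 1.03 in men only, bullying 0.91 in women; 1.0 elsewhere;
  unknown gender uses the female/male average on the log scale). Per-cell
  intercepts are calibrated by Monte-Carlo root finding
  (`calibrate_intercept()`, 2e5 common draws under a fixed internal seed so
  configurations are deterministic) so each cell hits its target prevalence:
  gender and age margins combined additively on the log-odds scale, which
  reproduces both sets of marginal prevalences to well within a percentage
  point in expectation.
* **Text.** Each stage becomes `messages_per_stage` (default 2) help-seeker
  messages interleaved with counselor filler. Planted phrases are embedded
  among pronounceable nonsense filler tokens that share no token with any
  lexicon phrase, and two planted phrases are always separated by at least
  one filler token, so the matcher can neither miss a planted occurrence nor
  find a spurious one: recovered counts equal planted counts *exactly*, the
  keystone end-to-end assertion. Every help-seeker message is padded with
  filler to the same character length (default at least 110 characters,
  raised per session when planted content requires), so the five stages have
  identical character mass and slicing at $f = s/5$ captures exactly stages
  $1..s$ — temporal tests need no slicing-ambiguity tolerance. A lexicon in
  which one category's phrase can match inside another's is rejected for
  rendering (`not uniquely plantable`), as is any filler/lexicon token
  collision.

`generate_corpus(..., render_text = FALSE)` skips rendering and returns only
counts, labels and demographics. Replicated statistical studies (parameter
recovery, CI coverage, temporal signatures, stratification specificity) run
on this count-level path — it is distributionally identical to
featurizing the rendered text, because rendering-then-matching reproduces
the planted counts exactly, and that exactness is itself asserted on rendered
corpora (10,000 sessions in the acceptance suite, every fraction in the unit
tests). This is what keeps hundred-replicate suites at the full reference
sample size inside ordinary desktop runtimes: the test suite uses 100
replicates at n = 17,564 for recovery and stratification checks, 100
replicates at n = 50,000 with a two-construct configuration for the
temporal-signature property, 10,000 rendered sessions for exactness, and
1,000 random instances for matcher-oracle equivalence.

### What the generator does and does not emulate

It emulates the sample structure (sizes, subgroup prevalences), the
count-feature/logistic-outcome dependence with reported effect sizes, and
stage-dependent construct intensity. It does not emulate language:
filler is nonsense by design (linguistic realism would break exact-recovery
testing), constructs are independent across categories (real constructs
correlate; an optional correlation extension was considered and rejected as
out of scope), message timing and dialogue coherence are absent, and
category phrase inventories are a handful of English phrases rather than
hundreds of Hebrew ones. Consequently, passing tests certify the *pipeline*
— extraction, modelling, stratification, trajectories — not any claim about
real chats.

One quantitative consequence deserves emphasis: with the reported
per-mention odds ratios and ~1.5 mentions per category per chat, the
variance of the true linear predictor is about 0.23, which bounds the
achievable held-out ROC–AUC near 0.63. The much higher discrimination
reported for the real corpus reflects signal — large phrase inventories,
higher match counts, correlated constructs — that cannot be reconstructed
from printed per-mention odds ratios alone, and the package makes no attempt
to inflate the generator toward it. The evaluation module is validated on
its own terms (metric arithmetic, oracle equivalence, split determinism),
and the realized synthetic AUC is reported as-is by the acceptance script.

## Numerical choices and degenerate inputs

* IRLS convergence: relative deviance change < 1e-10, max 100 iterations.
* Intercept calibration: 1-D root finding to tolerance 1e-10 on 2e5
  Monte-Carlo draws (prevalence error well under 1e-3); the closed form
  `qlogis(target)` is used when all coefficients are zero.
* HL binning: quantile breaks de-duplicated, so heavy ties reduce the bin
  count (and the degrees of freedom) rather than producing empty bins.
* Matching tie-break: leftmost start, then longest match; deterministic for
  any input.
* Empty text: zero counts, empty span list. Single-class strata, empty
  strata, constant non-intercept columns, rank-deficient designs: errors
  naming the stratum, never silent drops.
* Seeds: every stochastic entry point (`generate_corpus`, `split_holdout`,
  `evaluate_holdout`, `run_pipeline`) takes an explicit seed and restores
  the caller's RNG state.

## Known limitations

* Lexicon coverage is the whole game: the toy lexicon demonstrates the
  machinery but carries no clinical validity; real use requires the full
  construct inventories.
* Wald inference can be optimistic for very sparse categories in small
  strata; the package flags separation but does not implement penalised or
  exact logistic regression.
* The temporal design is repeated cross-sections of nested prefixes, so
  trajectory points are correlated across fractions within a stratum;
  the package reports per-fraction intervals and deliberately avoids
  cross-fraction tests.
* Counselor text is excluded from features by design; whether counselor
  language carries additional signal is an open question the package does
  not address.
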