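---
title: "Discovering predictive biomarker panels and Boolean expression signatures"
author: "BoolMark authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering predictive biomarker panels and Boolean expression signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BoolMark)
```

# Scope and model

BoolMark implements a two-phase procedure for deriving compact
predictive biomarker panels from an expression matrix (features ×
samples) labelled with three drug-response classes, and for turning the
selected panel into human-readable, response-group-specific *expression
signatures*.

The response classes are RD (responder), NR (non-responder) and PR
(poor responder). When response is measured as a log2 fold change of
Ki67 positivity under treatment, `labelFromKi67()` assigns RD for a
two-fold or greater decrease (log2 fc ≤ −1) and PR for a two-fold or
greater increase (log2 fc ≥ +1), NR otherwise. Two conventions are
deliberate and fixed: the thresholds are closed (±1 exactly takes the
outer class), and PR is defined symmetrically to RD. The second point
deserves emphasis because "poor responder" phrasing in the field is
sometimes stated as an increase *below* a bound, which read literally
overlaps the non-responder band; the symmetric rule is the only reading
that partitions the axis into three disjoint intervals, and it is what
the package implements.

Missing (undetectable) measurements are carried as `NA` and imputed by
`imputeMissing()` with independent draws from Uniform(0, 1) — the unit
being the minimal detectable amount, so sub-detection values are
uniformly spread below it. The bounds are configurable; every random
step in the package flows through an explicit integer seed and restores
the caller's RNG state.

# Phase 1: classifier, importance scores, greedy selection

## The evaluation engine

All feature-set comparisons go through one engine,
`evaluateFeatures()`: a multi-class support vector machine with a
linear kernel (one-vs-one pairwise decomposition, cost fixed at 1),
trained and tested under a repeated stratified holdout protocol
(`HoldoutPlan`; default 50 replicates of an 80/20 split). Each feature
is standardized to zero mean and unit variance using *training-set
statistics only*; the test samples are transformed with those same
statistics, so no information leaks from the held-out fold. With a
14/17/9 class balance a plain random 20% holdout can leave the
smallest class absent from training, so splits are stratified by class
by default (3 + 3 + 2 samples held out); an unstratified flag exists
and an absent class is then a hard error rather than a silent
degradation. Accuracy is the mean over replicates of the test-fold
accuracy; with constant test size this equals the micro-averaged
(pooled confusion-matrix) accuracy. Per-class precision and
sensitivity are derived from the replicate-summed confusion matrix,
and per-class AUCs from one-vs-rest decision scores pooled over
replicates. The SVM cost, the pairwise decomposition and the
stratification are the package's own choices where the underlying
protocol leaves them open; none is exposed to tuning by results.

A single `HoldoutPlan` fixes one integer seed per replicate, and the
same plan object is reused across every evaluation in a run — the
full-pool reference, every drop-out model, every greedy step, every
enumerated panel. This pairing is essential: accuracy differences then
reflect feature sets, not split noise.

## Drop-out importance and GFFS

`importanceScores()` removes each feature of a pool in turn and
re-evaluates, scoring

$$IS_i = -\frac{PA_i - PA_O}{PA_O},$$

so that a feature whose removal hurts accuracy gets a positive score.
`gffs()` then seeds a model with the top-ranked positive-impact
feature and walks once down the remaining ranked candidates, keeping a
candidate only when the shared-seed mean accuracy *strictly*
increases; candidates that leave accuracy unchanged are skipped, which
also guarantees the accepted-step accuracies are strictly increasing.
"Strictly greater" is an exact floating-point comparison on the paired
estimate, with no tolerance: under a shared plan the estimates are
deterministic, so a tolerance would only blur the rule. One evaluation
per candidate makes the selection cost linear — at most $2n$
classifier evaluations for $n$ features including the drop-out pass —
versus $n(n+1)/2$ for classical forward selection.

Two behaviours of this design are worth knowing. First, duplicated or
redundant features suppress each other's scores: removing one copy
costs nothing, so both score near zero. Second, when the classifier
*saturates* (reference accuracy 1.0 on the pool, which happens readily
on strongly separable data), no drop-out can increase accuracy and few
decrease it, so the positive-impact set can be small or even empty; an
empty candidate list yields an empty selection by contract, not an
error. The parameter-recovery checks in the test suite therefore
aggregate over the panels the pipeline actually produces across seeds
(pooled membership fraction), rather than forcing a panel out of a
saturated model.

## Exhaustive panel search

`enumeratePanels()`/`panelSearch()` evaluate every subset of a pool at
the requested sizes under the shared plan (a 16-feature pool gives 16,
120 and 4368 panels at sizes 1, 2 and 5). A configurable cap (default
$10^5$ panels) guards against accidental combinatorial explosions; the
best panel per size is the arg-max of mean accuracy with ties broken
by enumeration (lexicographic) order.

# Phase 2: binarization, truth tables, Quine–McCluskey signatures

`binarize()` discretizes expression per feature. Under the median
scheme each feature row is divided by its median across samples and
values > 1 become 1 (high). A value exactly at the median maps to 0 by
default: the underlying rule speaks only of values above or below the
median, so ties need a fixed documented convention, and mapping ties
low keeps "high" meaning strictly above the cohort's centre
(`tieHigh` flips it). The scheme is invariant to positive rescaling
and to monotone transforms that preserve the median ordering. For
noisy external cohorts a quantile-band scheme (`quantileBand(0.3,
0.7)`, linear-interpolation sample quantiles) calls values below the
30% quantile low and above the 70% quantile high, leaving the middle
band *indeterminate* (`NA`).

`groupTruthTable()` collects the distinct binarized patterns of one
response group; these are the minterms of the group's Boolean function.
`minimizeBoolean()` computes an exact minimum sum-of-products cover:
prime implicants by Quine–McCluskey pairwise merging, essential primes
first, and the residual cyclic core resolved exactly by
branch-and-bound enumeration of all minimum-cardinality covers
(Petrick's problem). Ties among minimum covers are broken by total
literal count, then by lexicographic order of the term patterns, so
the output is deterministic and unique — important because minimum
covers are generally not unique and the per-group signature IDs
(assigned in ascending term order) must be stable across runs.
Functions up to 20 variables are accepted; the intended regime is a
panel of ≤ 10 biomarkers with at most a few dozen observed patterns,
where the exact search is instantaneous. No external don't-care set is
supported: every observed pattern is ON, everything else OFF.

Each term of the minimized cover becomes one signature, with coverage
the fraction of the group's samples matching it (samples may match
several). Because the cover is logically equivalent to the observed
pattern set, every group sample matches at least one of its group's
signatures — the joint-coverage invariant the round-trip tests assert.
The same bit pattern can occur in two groups; signatures then overlap
and derivation warns but proceeds, since the predict-then-compare
workflow tolerates ambiguity.

`predictResponse()` matches a new sample's bit pattern against all
three signature sets under *consistent-with* semantics: a don't-care
literal is always satisfied, and an indeterminate sample bit satisfies
either literal value. All groups with at least one match are reported;
an empty result is an explicit no-call and multi-group matches are
never collapsed into a forced call. For external cohorts, medians and
quantiles are computed within that cohort by default (binarization is
cohort-relative); freezing discovery thresholds is possible by
binarizing manually.

# The synthetic cohort generator

`simulateCohort()` emulates the discovery setting: 40 samples in
groups of 14/17/9, 100 features of which 10 are informative, 0.16 %
missing cells — all configurable. Log-scale abundances are Normal with
a per-feature baseline mean drawn from Normal(10, 1) and within-group
SD `noiseSd` (default 1). Informative features receive a group mean
shift of magnitude `effectSize × noiseSd` (default effect size 3) with
shift patterns — RD-high, PR-high, NR-high, RD-low, PR-low, monotone
RD>NR>PR — assigned cyclically, so both directions of differential
expression occur as they do in real marker heatmaps. The baseline of
10 keeps abundances comfortably positive, which the median
binarization scheme requires.

What the generator does *not* model: mass-spectrometry intensity
distributions (heavy tails, intensity-dependent variance),
missingness that depends on abundance (real "undetectable" values are
left-censored, not missing at random), correlated features, and batch
effects. Passing tests on this generator therefore demonstrate that
the algorithms recover planted structure under clean Gaussian
assumptions — they do not certify performance on real
pharmacoproteomic data, where the DEP filter and the SVM face heavier
noise and the informative fraction is far smaller.

# Numerical choices and degenerate inputs

* ANOVA is a classical one-way fixed-effects F computed row-wise from
  explicit sums of squares (validated in the tests against
  `stats::oneway.test(var.equal = TRUE)` to 1e-10). Zero
  within-group variance is handled by convention: p = 0 when group
  means differ, p = 1 when every value is identical. Features are
  tested on abundances as provided; a log2 option exists but is off by
  default, as is the optional Benjamini–Hochberg correction (the
  pre-filter is intentionally a raw p < 0.05 screen).
* The DEP filter uses strict inequality p < α, with α permitted up to
  1 so the vacuous filter is expressible.
* A feature constant across a training fold would give a 0/0 after
  standardization; its scale is set to 1 (the centred column is all
  zeros), which contributes nothing to the kernel rather than
  propagating NaN.
* Importance ties are broken by original pool order, and the
  importance score is undefined (an error) when the reference accuracy
  is 0.
* Test sizes in this package's own suite are scaled to the problem:
  parameter recovery runs 10 seeds of the default 40 × 100 cohort with
  50-replicate plans; minimization is cross-checked against a
  brute-force prime-implicant/set-cover oracle on 200 random functions
  of up to 6 variables.

# Known limitations

* Exact minimization is exponential in the worst case; the guard at 20
  variables does not make adversarial inputs fast, it only rejects
  absurd ones. Panels beyond ~12 biomarkers should be compacted first.
* The greedy pass is single-pass by design: skipped features are never
  revisited, so feature interactions that only help in combination with
  later acceptances can be missed. This is the deliberate trade-off
  that buys linear cost.
* On saturated classifiers (accuracy 1 on the pool) the drop-out score
  carries no signal and the pipeline legitimately returns no panel;
  enlarging the holdout plan does not change this, since the estimates
  are exact ties, not noisy ones.
* Signature coverage is in-sample; it is not a calibrated probability
  of class membership for external cohorts.
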