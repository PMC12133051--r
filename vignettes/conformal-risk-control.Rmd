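---
title: "FNR-controlled prediction sets by conformal risk control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FNR-controlled prediction sets by conformal risk control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(setconform)
```

## The model

`setconform` post-processes a multiclass classifier. Its input is a score
matrix $s \in [0,1]^{n \times K}$ — one row per sample, one column per class
— plus a table of true labels, where a sample may carry one label, several
(biologically composite cases), or none (subtype unknown). Scores are taken
as-is: rows are **not** assumed to be probability simplexes, because
one-vs-rest classifiers routinely score two confusable classes high
simultaneously, and renormalizing would destroy exactly the signal that
prediction sets exploit. Scores are validated to $[0,1]$ and never rescaled.

For a threshold $t$ the prediction set is $C_t(x) = \{k : s_k(x) \ge t\}$,
and the per-sample loss is the fraction of true labels missed,
$L(t) = |Y \setminus C_t|/|Y|$, which reduces to the 0/1 miss indicator for
single-label truth and is monotone nonincreasing in the set (the property
conformal risk control requires), bounded by $B = 1$.

Split conformal risk control selects, from $n$ labeled calibration samples,

$$\hat\lambda = \max\Big\{\, t :
  \tfrac{n}{n+1}\,\hat R(t) + \tfrac{B}{n+1} \le \alpha \Big\},$$

where $\hat R(t)$ is the mean calibration loss. If future samples are
exchangeable with the calibration set, prediction sets formed at
$\hat\lambda$ satisfy $\mathbb{E}[\mathrm{FNR}] \le \alpha$ regardless of
how well the underlying classifier is trained or calibrated. That is the
entire assumption: exchangeability. Nothing is assumed about score
distributions, class balance, or correctness of the classifier.

### Exact threshold search

$\hat R$ is a right-moving step function: it changes only where $t$ crosses
a score that some sample assigns to one of its true labels. Calibration
therefore scans the exact candidate set
$\{0\} \cup \{\text{unique true-label scores}\}$ rather than a grid; between
two consecutive candidates the risk is constant, so the supremum of feasible
thresholds is always attained at a candidate. The test suite confirms
agreement with a 10,001-point dense-grid brute force (written directly from
the loss definition) to within one grid step on 200 random instances.

### Inclusion rule at the boundary

Classes enter the set when $s_k \ge \hat\lambda$ (closed rule). A strict
rule ($>$) differs only for scores exactly equal to $\hat\lambda$; the
closed rule is the one under which the candidate-set search is exact,
because the risk then changes precisely *at* the candidate values. This was
a genuinely open choice and is recorded as such; with continuous scores the
two rules coincide almost surely.

### Feasibility

Even the all-classes set ($t = 0$, zero loss) cannot certify a tolerance
below $B/(n+1)$, because of the conformal correction term. `calibrate()`
refuses such tolerances with an error carrying the minimum achievable
value (`minFeasibleAlpha(n, B)`) instead of silently returning
$\hat\lambda = 0$; grid scans (`lamhatCurve()`, `selectAlpha()`) flag
infeasible entries rather than dropping them.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | — | FNR tolerance in $(0,1)$; the guarantee is $\mathbb{E}[\mathrm{FNR}] \le \alpha$ |
| `lossBound` | 1 | per-sample loss bound $B$; 1 for the fractional FNR loss |
| `calFraction` | 0.9 | calibration share in each shuffle-split run (a 90/10 split) |
| `floor` (top-1 baseline) | 0.5 | minimum score for the point classifier to emit its top class; below it the baseline declines to predict |
| `alphaGrid` | 0.05–0.50 by 0.025 | scan range for empirical tolerance selection, covering the working tolerances 0.075–0.30 |
| `nRuns` | context-dependent | shuffle-split repetitions; aggregates carry Monte-Carlo standard errors $\mathrm{sd}/\sqrt{n_\mathrm{runs}}$ |

Percentages in reports are displayed rounded to two decimals; `lamhat` and
all stored quantities keep full precision (display rounding only).

## Evaluation conventions

* **Unknown-subtype samples** (empty truth) are never scored for loss —
  `fnrLoss` rejects them — but they do count in set-size and emptiness
  accounting, since empty prediction sets are exactly how a model should
  respond to inputs it does not recognize.
* **Multi-label truth** uses the fractional loss by default (miss one of two
  true subtypes → loss 0.5). An all-or-nothing variant is available via
  `evaluateSets(..., lossType = "allOrNothing")`, since either convention is
  defensible for composite cases; the fractional form is the one the
  calibration loss uses, so the two stay consistent by default.
* **Per-class strata** use single-label samples only; multi-truth samples are
  summarized separately (`multiTruthFnr`), so class-level FNRs are not
  diluted by fractional losses.
* **The uncalibrated baseline** is top-1 membership with a 0.5 floor: a
  maximum score below the floor yields an empty prediction. This matches how
  the upstream classifiers are used in practice (a default softmax cutoff)
  and makes the baseline comparable on unknown-subtype cohorts. The floor is
  configurable.
* `compareMethods()` and `selectAlpha()` reuse identical shuffle splits
  across methods and tolerances (one split stream per seed), so comparisons
  are paired: the baseline row is exactly constant across tolerances, and
  tolerance effects are not confounded with split noise.
* **Tolerance selection** maximizes the cross-validated mean proportion of
  certain (single-class) sets, not a single whole-data evaluation; ties break
  toward the smallest tolerance, which carries the stronger guarantee at
  equal certainty. The `lamhatCurve()` shown alongside is calibrated once on
  the whole data (the per-run thresholds vary slightly with each split; the
  whole-data curve is the deterministic summary).

## The synthetic generator

`simulateScores()` emulates the statistical structure of RNA-seq subtype
classifier outputs so that every other module is testable without cohort
data:

* **Imbalanced classes.** The `presetAlliumLike()` preset has 14 subtype
  labels with frequencies from 22% down to 2%.
* **Scaled-beta, one-vs-rest scores.** True-label scores draw from
  Beta(24, 1) (mean 0.96), background from Beta(0.5, 10) (mean ≈ 0.05),
  confusable classes from Beta(17, 3) (mean 0.85). Off-target classes are
  independent given the truth — deliberately *not* a Dirichlet/simplex
  model, which could never produce two simultaneously high scores.
* **Confusable pairs.** A $K \times K$ weight matrix gives each true class a
  propensity to elevate specific off-target classes; the preset wires
  PAX5 P80R ↔ PAX5alt and BCR::ABL1 ↔ BCR::ABL1-like, echoing the
  confusions real subtype classifiers exhibit.
* **Composite and unrecognized samples.** 5% of preset samples carry two
  true labels (both drawing on-target scores — the union structure); 5% are
  out-of-distribution: empty truth, all-background scores.
* **Determinism.** One integer seed drives a single explicitly scoped random
  stream (`withr::with_seed`); identical seeds give identical matrices, and
  no global RNG state leaks.

Every preset number is illustrative — chosen once to mirror the qualitative
structure above, not fitted to any cohort. What passing tests on this
generator do show: the finite-sample guarantee, monotonicity, and the
error/precision trade-off, all of which are distribution-free. What they do
not show: cohort-specific magnitudes (real per-subtype FNRs, real set-size
profiles, batch effects, calibration/validation distribution shift), which
depend on actual classifier outputs.

## Problem sizes and numerical choices

* The guarantee checks run 1,000 shuffle-split repetitions of an 851-sample
  preset cohort at the working tolerances (0.075 and 0.30 at the extremes);
  with MC standard errors near 0.1 percentage points, 1,000 runs resolve the
  one-sided bound comfortably. Assertions allow three MC standard errors of
  one-sided slack.
* Feasibility and constraint comparisons use an absolute epsilon of 1e-12 so
  that exact-arithmetic boundary cases (e.g. an adjusted risk exactly equal
  to $\alpha$) are accepted, as the closed-form selection rule intends.
* Argmax ties in the top-1 baseline break toward the earlier class column —
  a documented, deterministic convention.
* Shuffle splits take the first $\lfloor 0.9 n \rfloor$ positions of a
  permutation for calibration; both partitions are required nonempty, and an
  infeasible tolerance for the realized calibration size fails before any
  run.

## Limitations

* One global threshold is calibrated; there is no class-conditional
  (Mondrian) calibration, so per-class FNRs can sit above $\alpha$ for hard
  classes even while the marginal guarantee holds — the stratified reports
  make this visible rather than hiding it.
* Only the FNR loss is controlled; false-positive-rate or set-size risks are
  out of scope.
* The guarantee is in expectation over exchangeable draws, not per sample or
  per class, and distribution shift between calibration and deployment
  breaks exchangeability — recalibrate on data from the deployment
  distribution.
* The tool begins at classifier scores: no expression preprocessing, batch
  correction, or classifier training.
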