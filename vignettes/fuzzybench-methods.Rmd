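---
title: "Methods: fuzzy MCDM benchmarking of hybrid diagnosis models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fuzzy MCDM benchmarking of hybrid diagnosis models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzybench)
```

## Overview

`fuzzybench` evaluates and ranks *hybrid diagnosis models* — pairs of a
filter feature-selection technique and a classifier — on clinical
tabular data with a 3-level severity outcome. Its three phases are
deliberately decoupled: Phase 1 produces a complete, normalized,
balanced patient table; Phase 2 produces a decision matrix of 15 hybrid
models by 7 performance criteria; Phase 3 ranks the models by fuzzy
opinion scores. Each phase is exposed as ordinary functions and as CLI
subcommands, so every intermediate artifact can be inspected, replaced,
or re-run in isolation.

## Triangular fuzzy numbers

All expert judgment in the framework flows through triangular fuzzy
numbers (TFNs). A TFN $(a, b, c)$, $a \le b \le c$, has membership
rising linearly from $a$ to 1 at the mode $b$ and falling to 0 at $c$.
The two built-in five-term vocabularies (importance ratings 1–5 and
difference-from-ideal opinions) share the supports
$(0,.1,.3), (.1,.3,.5), (.3,.5,.75), (.5,.75,.9), (.75,.9,1)$.

Arithmetic follows the extension-principle componentwise rules; the
product and quotient rules are first-order approximations, which we take
as definitional since no exact alternative is in common use for this
method family. Two numerical choices deserve note:

* **Degenerate triangles.** When $b = a$ or $b = c$ the rising or
  falling edge of the membership function becomes $0/0$; we define the
  edge as a step so membership at the mode is always 1 — the continuity
  limit of shrinking the edge width.
* **Non-negative domain.** Products and quotients of mixed-sign TFNs can
  violate $a \le b \le c$. Every scale in this framework lives in
  $[0, 1]$, so the library is restricted to non-negative TFNs and raises
  on violations rather than silently reordering.

Centroid defuzzification $(a + b + c)/3$ is linear in the components,
so "average the TFNs then defuzzify" and "defuzzify then average" agree
to machine precision; the test suite asserts this identity at $10^{-12}$
because FDOSM's group aggregation silently relies on it.

## FWZIC criterion weighting

Experts rate each feature's importance directly on the 5-point scale (no
pairwise comparisons, hence no consistency ratio to violate). Each
rating's TFN is divided by the fuzzy sum of the expert's own row — the
rating becomes the expert's *relative share* of importance — then cells
are averaged over experts componentwise. The aggregation order for the
final crisp weights was genuinely open: we defuzzify each criterion's
TFN first and then rescale the crisp values by their total, because this
is the only order that guarantees exact unit sum for arbitrary panels;
property tests exercise unit sum, expert anonymity, criterion
permutation equivariance and rating monotonicity on random panels, and a
scalar brute-force oracle reproduces the vectorized path exactly on all
small panels.

One boundary case is rejected by design: an expert who rates *every*
criterion at the scale minimum produces a row sum whose lower support is
0, making the fuzzy quotient undefined. We raise a domain error rather
than perturb the scale; a panel carrying literally no preference
information has no meaningful weights.

Weights are computed per feature-selection technique on that technique's
surviving features only, so the same feature can legitimately carry
different weights in different hybrid branches. Weight injection
multiplies each selected, normalized feature column by its weight — the
estimation-parameter and error terms sometimes written around this
transform are fixed at 1 and 0, the only reading consistent with
"multiply each weight by its data".

## Phase 1 choices

The order clean → impute → normalize → SMOTE is fixed: SMOTE's
nearest-neighbour geometry needs complete data on a common scale.
Defaults and rationale:

* **Encoding.** Categorical levels are coded 0, 1, … alphabetically
  (deterministic, persisted in a codebook); the class is coded
  light = 0, medium = 1, intense = 2. Encoded categoricals participate
  in imputation, distances and interpolation as numbers — the convention
  the emulated study applies silently; synthetic categorical cells may
  therefore be fractional.
* **Mean imputation** is applied to every column; a fully missing column
  is an error naming the column.
* **Min–max normalization** maps constant columns to 0 instead of
  erroring, keeping degenerate synthetic inputs runnable.
* **SMOTE** upsamples every minority class to the majority count with
  $k = 5$ neighbours (the method's customary default; the emulated study
  does not state $k$). Synthetic rows are convex combinations of
  same-class rows, so they provably stay inside the class's
  componentwise hull — a property test.

## Feature selection

χ² and information gain operate on contingency tables; numeric features
are discretized into 4 equal-frequency bins (configurable) — standard
filter practice. ReliefF uses normalized absolute differences for all
features (the table is fully numeric after Phase 1), $k = 10$ neighbours
by default, and all rows in order as the instance sample, which makes it
deterministic without subsampling. The default survival rule is
"score > 0" with alphabetical tie-breaking; top-$k$ and threshold rules
are exposed because the published survivor counts (39/38/41 of 48) are
data-dependent and not re-derivable without the original records.

## Hybrid models and the decision matrix

The 15 alternatives follow a fixed grid: feature-selection technique
outermost (ReliefF, information gain, χ²), classifier innermost
(decision tree, SVM, naive Bayes, KNN, AdaBoost). Classifier
implementations are the field's standard ones — `rpart`, `e1071` (SVM,
naive Bayes), `caret::knn3` — with their common defaults (KNN $k = 5$,
RBF SVM); multiclass AdaBoost (SAMME, 50 rounds of depth-1 stumps) is
implemented in-package. Hyperparameters are recorded in the run
manifest.

Quality metrics are micro-averaged: for single-label multiclass
prediction, pooled precision, recall and F1 all collapse to accuracy —
the structural reason a published benchmark matrix can show identical
accuracy/F1/recall cells per row — and the implementation asserts this
identity on every evaluation. AUC is macro one-vs-rest. The 66/34
stratified split rounds per class, reproducing 513/264 on 777 balanced
rows.

**Timing.** Wall-clock train/test time are genuine cost criteria, but
they are hardware noise: feeding them into the ranking makes a pipeline
non-reproducible. The default configuration therefore sets
`timing = "none"` — both time criteria are constant 0, which the opinion
surrogate maps to "No difference" for every alternative (a constant
column carries no discriminating information), and the whole pipeline is
bit-reproducible under a fixed seed. `timing = "measured"` restores real
measurements for benchmarking runs where reproducibility of the ranking
is not required.

## FDOSM ranking

The ideal solution takes each cost column's minimum and each benefit
column's maximum; a configured *critical value* can override either for
criteria whose optimum is interior (the classic blood-pressure case) —
supported but unused for the seven metric criteria. Expert opinion
matrices are first-class file inputs; `auto_opinions()` is an explicitly
labelled surrogate that bins each cell's normalized gap from the ideal
($g = |v - A^*_j| /$ column range) at edges $0.1, 0.3, 0.55, 0.8$ into
the five terms, closed on the left bin. Scores are centroid means of
the opinion TFNs, bounded in $[0.1\overline{3}, 0.88\overline{3}]$
(all-"No difference" and all-"Huge difference" respectively); group
scores average per-expert scores. Ranks are emitted twice: ordinal
(ties broken by alternative order) and dense (tied scores share a rank),
since published rankings of this method family use the dense
convention.

## The synthetic generator

The generator emulates the study cohort the framework was built around:
538 rows, class counts 241/259/38, the full 48-feature schema with the
published categorical vocabularies and numeric ranges (one range printed
reversed in the source table, 609–85, is read as 85–609), and sentinel
missingness at 5% on the medical-test columns flagged as incomplete
(the exact per-feature percentages are not published). Ten
behavioural/medical features carry the planted class signal by default —
class-conditional category probabilities or class-shifted truncated
normals — with effect size 0.8, chosen so the signal is strong but not
trivially separable, which is what a cohort separable at ~99% accuracy
by a decision tree looks like.

What the generator does **not** emulate: inter-feature correlation
beyond the shared class, realistic ASD epidemiology, informative
missingness, or the actual expert panel's judgments. Passing tests
therefore demonstrate that the machinery is correct and well-calibrated
on data of the study's shape, not that the published per-model metric
values are reproduced — those depend on the original, on-request
records. Two calibration properties are tested: all three filters rank
every planted feature above every noise feature (across 5 seeds), and
with zero effect size the test accuracy of a hybrid model stays within
3σ of chance.

## Problem sizes and runtime

Unit and property tests run on panels up to 5×10, toy tables of tens of
rows, and scaled cohorts of 120–240 rows; the acceptance suite runs the
full default cohort (538 → 777 balanced rows, 48 features, all 15
hybrids) twice to verify bit-reproducibility. The full default pipeline
takes on the order of a minute on a single CPU.

## Known limitations

* Survivor-set sizes and per-model metric values from the original
  study are context, not targets: they require the non-public records
  and unprinted expert ratings.
* The feature-selection threshold question is inherited from the method
  family: "score > 0" is a pragmatic default, not a principled stopping
  rule.
* Fuzzy product/quotient are approximations; alternative t-norm-based
  arithmetic is out of scope, as are trapezoidal numbers, other
  defuzzifiers, and other MCDM families (TOPSIS, VIKOR, AHP).
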