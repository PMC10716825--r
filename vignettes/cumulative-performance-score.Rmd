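---
title: "The cumulative performance score: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cumulative performance score: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlcps)
```

## The problem

Choosing the "best" of several trained classifiers from a panel of
evaluation metrics — accuracy, precision, recall, F1, average precision,
ROC AUC, and so on — is awkward because the metrics disagree: each one
measures a different aspect of performance, and a model that tops one
column rarely tops them all. Eyeballing the table invites subjective,
metric-by-metric judgement calls; collapsing it to a single defensible
number is what this package does.

## The score

Take one model's metric values $d_1, \dots, d_n$ (all on a common scale,
by default $[0, 1]$) and draw them as rays from the origin of a polar
plane, equally spaced: ray $i$ has length $d_i$ and sits at angle
$(i - 1)\,\theta$ with $\theta = 2\pi / n$. Joining the ray tips yields a
closed polygon, and the plane decomposes into $n$ triangles, one per
adjacent ray pair. Each triangle with sides $d_i$ and $d_{i+1}$ and
included angle $\theta$ has area $\tfrac{1}{2} d_i d_{i+1} \sin\theta$, so
the cumulative performance score is the total polygon area

$$
\mathrm{CPS} \;=\; \frac{1}{2}\,\sin\theta \sum_{i=1}^{n} d_i\, d_{i+1},
\qquad d_{n+1} \equiv d_1 .
$$

The wrap-around term $d_{n+1} = d_1$ is what closes the polygon; without
it the last and first rays would bound no triangle and the "total area"
reading would fail. `compute_mlcps()` implements exactly this sum, and the
test-suite checks it against an independent surveyor's (shoelace) formula
applied to the Cartesian vertices
$(d_i \cos((i-1)\theta),\, d_i \sin((i-1)\theta))$.

Properties that follow directly, all asserted as tests:

* **Bounds.** For values in $[0, u]$, the score lies in
  $[0,\; \tfrac{n}{2}\sin(2\pi/n)\,u^2]$, the maximum being the regular
  polygon with every ray at $u$ (2.0 for four metrics at $u = 1$,
  $3\sqrt{3}/4 \approx 1.299$ for three, $\tfrac{5}{2}\sin(2\pi/5)
  \approx 2.378$ for five).
* **Quadratic scaling.** Scaling every metric by $c$ scales the area by
  $c^2$ — rankings are invariant to a common rescaling, absolute scores
  are not, which is why a shared scale across metrics matters.
* **Monotonicity.** With all other rays positive, increasing any single
  metric strictly increases the area; coordinate-wise dominance therefore
  implies a higher score.
* **Ordering.** The score is invariant to cyclic rotation and reversal of
  the metric ordering but *not* to arbitrary permutations (adjacent
  products change). The column order of the input table is the ray order,
  it is shared by every model in a table, and it is echoed in every report
  so that comparisons are always like-for-like.

`normalized_score` divides the area by the all-at-$u$ maximum above. It is
a convenience for reading scores on $[0, 1]$; the raw area is the primary
output.

## Weights

Each metric may be assigned a non-negative weight; the weighted score uses
$d_i^{w} = d_i \cdot w_i$ in place of $d_i$. Unmentioned metrics keep
weight 1, so supplying no weights is identical to all-ones weighting (a
tested identity). A weight of exactly zero *excludes* the metric: the ray
disappears, $n$ shrinks, and $\theta$ is recomputed on the reduced set —
tested as exact equality with scoring the reduced vector directly.
Weights above 1 are allowed; they can push values past the declared upper
bound, which triggers a warning (and clamping of the normalized score)
rather than an error, since the raw area remains well defined.

Weighting is powerful but easily abused: a heavy weight on one metric can
overwhelm the rest of the panel, and weight choices encode subjective
priorities. The package applies whatever weights it is given and leaves
that judgement to the analyst.

## Degenerate and invalid input

* Fewer than three effective metrics (after exclusion) cannot form a
  polygon; $n = 2$ would give $\sin(2\pi/2) = 0$ identically. This errors
  loudly rather than returning 0.
* Negative ray lengths are rejected. Metrics on $[-1, 1]$ (Matthews
  correlation) must be rescaled first — `rescale_unit()` maps them to
  $[0, 1]$, and the panel offers the MCC only in rescaled form.
* Missing cells are errors, never implicit zeros: a zero ray annihilates
  the two triangle terms it touches, which would silently distort a
  comparison.
* Numerical equality in the tests is asserted at `1e-9` absolute (the
  computation itself is a short sum of products; observed deviation from
  the oracle is at machine precision, ~`4e-16`).

## The SD baseline

A traditional informal rule prefers the model whose metrics are most
*consistent*, i.e. have the smallest standard deviation across the panel.
`compare_rankings()` reports both orderings because they can disagree in
an instructive way: a model stuck at 0.5 on every metric has SD 0 — the
best possible consistency — while a strong model at
$\{0.95, 0.90, 0.92, 0.93\}$ has a larger SD but a far larger polygon.
Dispersion ignores magnitude; the area captures both. The SD column is
always computed from the raw, unweighted metrics (sample SD, $n - 1$
denominator) even when the score is weighted: it is a descriptive
baseline of the panel as measured, not of the reweighted geometry.

When a second table is supplied (the same models evaluated on held-out
data), the report adds each model's rank in the second table, the count of
models whose rank is unchanged, and the Spearman correlation of the two
score vectors — a direct check of whether selection by this score
generalises from training to test data.

## What the synthetic generators emulate

No external dataset ships with the package; two generators create inputs
with known ground truth.

`simulate_classifier()` draws labels Bernoulli($p$) and a latent score
$z \sim N(\pm s/2, 1)$ per class, where $s$ is the `separation`. Reported
scores are calibrated posterior probabilities
$\mathrm{plogis}(\mathrm{qlogis}(p) + s\,z)$ — for unit-variance Gaussians
the log-likelihood ratio is linear in $z$ — and hard labels come from
thresholding at 0.5. Two consequences anchor the tests: expected ROC AUC
is $\Phi(s/\sqrt{2})$ in closed form, and at $s = 0$ the posterior
collapses to the prior, so the classifier predicts the majority class and
its accuracy approaches $\max(p, 1 - p)$ while its AUC is exactly 0.5
under the midpoint tie convention. Defaults ($p = 0.5$, threshold 0.5)
describe a balanced problem; imbalance is exercised explicitly in tests.
This generator emulates a well-calibrated probabilistic classifier only —
real models are miscalibrated, scores are rarely Gaussian, and classes
rarely cleanly unimodal — so passing tests demonstrate correctness of the
metric and scoring pipeline, not performance claims about real data.

`make_metric_table()` produces metric tables directly: `random`
(i.i.d. uniform cells), `dominated` (each model strictly exceeds the next
in every metric, drawn from disjoint bands of $[0,1]$, so the true ranking
is known and must be recovered under any column order), and `constant`
(all models identical; every scorer must tie them, and ties share the
minimum rank with an explicit flag, ordered by model name for
deterministic output).

All randomness flows through an explicit `seed` argument and
`withr::with_seed()`, leaving the caller's RNG stream untouched.

## Metric panel choices

The supported panel is accuracy, balanced accuracy, precision, recall,
specificity, F1, rescaled MCC, average precision and ROC AUC; the default
selection is the seven-metric subset without specificity and MCC. Three
deliberate choices:

* **Undefined metrics error.** Precision with nothing predicted positive,
  specificity with no negatives, MCC with a zero margin — each raises an
  error with a remediation hint instead of returning 0 or `NaN`, for the
  same zero-ray reason as above.
* **ROC AUC** uses the Mann–Whitney rank statistic, equivalent to the
  trapezoidal rule over unique thresholds with ties contributing one half.
  Scores equal to the labels give 1, anti-correlated scores 0, constant
  scores 0.5.
* **Average precision** is the step-wise (non-interpolated) flavour,
  $\sum_k (R_k - R_{k-1}) P_k$ over decreasing unique thresholds; tied
  scores enter at the same threshold. Expected values in the tests were
  frozen from an independent reference implementation.

## Problem sizes

The test-suite and the acceptance script run the oracle comparison on
1,000 random panels ($n \in 3..12$), dominance recovery over 100 seeds,
and the end-to-end simulation at 10,000 instances per classifier — sizes
at which Monte-Carlo noise on the reported rates is well below the
asserted tolerances (binomial SE $\approx 0.005$ at $n = 10{,}000$)
while the whole suite completes in well under a minute.

## Known limitations

* The score depends on metric ordering; the package pins and reports the
  ordering rather than trying to define an order-free variant.
* No uncertainty is attached to a score (no bootstrap/CI is defined for
  it), so small score differences should not be over-read.
* Binary classification only; multi-class averaging is out of scope.
* Raw areas are only comparable across tables with the same number of
  metrics and the same upper bound — use `normalized_score` when
  geometries differ.
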