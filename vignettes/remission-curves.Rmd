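---
title: "Remission curves, truncated-course prediction and boosted efficacy classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Remission curves, truncated-course prediction and boosted efficacy classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remcurve)
```

## The remission-curve model

Pain relief under physiotherapy is treated as a saturating process: a
patient's VAS score at session $x$ follows

$$y(x) = \ell + \frac{H}{1 + e^{a + bx}}, \qquad H = K - \ell,$$

a decreasing sigmoid between an upper asymptote $K$ (the pain level the
course starts from) and a lower asymptote $\ell$ (the best achievable
relief, fixed at 0 by default). The inflection $x^* = -a/b$ is the onset
of relief and $b \ge 0$ the descent rate; between them they express the
two clinically salient features of a remission course, *when* relief
starts and *how fast* it proceeds.

Model assumptions worth stating explicitly:

* **Monotone relief.** With $b \ge 0$ the curve never rises; transient
  flare-ups are treated as measurement noise, not signal.
* **Fixed asymptotes.** $K$ is not estimated: the MCSD argument places it
  1.2 VAS points above the first rating ($K = \mathrm{VAS}_1 + 1.2$,
  capped at the scale top, so $K = 10$ whenever
  $\mathrm{VAS}_1 \ge 8.8$). The lower asymptote defaults to 0 — complete
  relief is the theoretical floor. `fit_patient(lower = )` exposes a
  nonzero fixed floor for sensitivity analysis, but $\ell$ is never
  estimated: with 10 points and a fixed $K$ a third free parameter is
  weakly identified and trades off almost linearly with $b$.
* **Sessions as the time axis.** Ratings are taken before each session at
  roughly fixed intervals, so $x = 1, \dots, 10$ is an adequate clock.

### Fitting

Only $(a, b)$ are estimated, by bounded least squares (L-BFGS-B with
analytic gradient; $b \in [0, 10]$, $a \in [-50, 50]$, `factr = 10`,
up to 1000 iterations). The SSE surface has one treacherous region: along
$b = 0$, $a \ll 0$ the curve degenerates to a constant at $K$, and a
single start can slide into that basin for slowly-declining
high-asymptote series. The optimiser therefore runs from a small
deterministic battery of starts — trial rates $b_0 \in \{0.1, 0.5, 1.5\}$
with $a_0 = -b_0 x_{\mathrm{mid}}$ ($x_{\mathrm{mid}}$ = session whose
score is nearest the asymptote midpoint, fallback 5.5), plus an analytic
*chord start* that solves $a + bx = \log(H/(y-\ell) - 1)$ exactly through
the first and last interior observations — and keeps the best final SSE.
Everything is deterministic; the returned parameters never have a larger
SSE than the best start (fits that fail to improve are flagged
`converged = FALSE` but still returned, so downstream tables keep their
row sums).

Degenerate inputs are handled explicitly: a constant series below $K$
collapses to $b = 0$ with undefined per-patient $R^2$ (its total sum of
squares is zero); a two-point series is interpolated exactly by the chord
start and flagged `exact_fit`; fewer than two points is an error.
Predicted VAS values are clipped to $[0, 10]$ before any scoring.

### Coefficients of determination

Per patient, $R^2 = 1 - SS_{res}/SS_{tot}$ about the patient's own mean.
The cohort-level summary pools sums before dividing,
$R^2_{global} = 1 - \sum_i SS_{res,i} / \sum_i SS_{tot,i}$, rather than
averaging per-patient values: pooling weights each patient by the
variability of their own series and is the natural reading of a "global"
coefficient; the mean of per-patient values is computable from `fits.csv`
if wanted.

## Truncated-course prediction and the MCSD rules

`fit_truncated()` refits on sessions $1..m$ (the asymptote rule still
uses the session-1 score) and `predict_final_vas()` extrapolates to
session 10. Two success notions, both driven by the 1.2-point MCSD:

* **Effectiveness**: a course is clinically effective when the VAS falls
  by *strictly more than* 1.2 points; the prediction succeeds when the
  predicted and observed classifications agree. Both declines are
  anchored at the *measured* first score (the same anchor the asymptote
  rule uses), not at the fitted curve value at $x = 1$.
* **Remission magnitude**: success when the predicted final score is
  *within* 1.2 points (inclusive) of the measured one.

The strict/inclusive boundary conventions follow the clinical wording.
Both comparisons carry a $10^{-9}$ guard so that differences which are
exactly 1.2 on the 0.1-point recording grid land on the intended side
despite binary floating-point representation (e.g. $5.2 - 4.0$ exceeds
1.2 by $2 \times 10^{-16}$ in double arithmetic).

Success counts per treatment length are compared by Pearson chi-square
without continuity correction (counts are in the hundreds; the correction
would only blunt the statistic). After an overall significant result the
cells are pooled — lengths 2–4 vs 5–9 for effectiveness, and 2–4 / 5–7 /
8–9 with consecutive pairwise 2×2 contrasts for remission magnitude — to
limit the number of comparisons. `pooled_group_comparison()` refuses
non-partitions and single groups.

## The gradient-boosting classifier

The boosting machine is implemented from scratch as literal
forward-stagewise least-squares boosting: $F_0(x) = 0$, $r_i = y_i$, and
for $m = 1..M$ a CART regression tree fitted to the residuals is added
with shrinkage $\mu$, after which $r_i \leftarrow r_i - \mu \hat f_m(x_i)$;
$F_M(x) = \sum_m \mu \hat f_m(x)$. Three design points deserve comment:

* **Squared-error loss on a binary label.** The efficacy outcome is 0/1,
  yet the boosting recursion is the least-squares one. We implement it
  literally (scores clipped to $[0,1]$ serve as class probabilities)
  because that *is* the specified algorithm; `gbm_config(loss =
  "logistic")` provides deviance boosting with Newton leaf steps for
  comparison. Empirically the two rank test-set patients almost
  identically at these sample sizes.
* **Depth vs leaf count.** The base learner is bounded both by
  `max_depth` (4, the tuned value, depth-wise growth as in scikit-learn)
  and by a terminal-node budget `max_leaves` ($L$, defaulting to
  $2^{\text{depth}}$ so the depth bound is the active one). Under the
  $d = L - 1$ convention for interaction depth the default trees allow
  up to 16 leaves.
* **Determinism.** Split thresholds are midpoints between consecutive
  distinct sorted feature values; gain ties break to the lower feature
  index, then the lower threshold. The only randomness is the seeded
  square-root feature subsampling at each split (and row subsampling if
  `subsample < 1`, off by default), driven by a single seed (default 10).

Feature importance is total split-gain (SSE reduction) per feature,
normalised to sum to one. `train_test_split()` implements the seeded 7:3
partition (first $\lceil 0.7 n \rceil$ rows of a uniform permutation).

The implementation is cross-checked in the test suite against xgboost
run as plain squared-error boosting (`lambda = 0`, `gamma = 0`,
`base_score = 0`, exact splits, no subsampling): predictions agree to
$10^{-6}$ — the residual difference is xgboost's float32 arithmetic.

## ROC evaluation

`roc_curve()` enumerates one operating point per unique score (score
$\ge$ threshold called positive) plus the all-negative endpoint;
`auc()` is the trapezoidal area, which for such curves equals the
Mann–Whitney concordance probability with ties counted one half — an
identity the tests verify to $10^{-12}$. Higher scores mean predicted
good efficacy.

The AUC confidence interval defaults to DeLong's variance estimate
(via pROC) because it is the standard asymptotic interval for a single
AUC; a seeded stratified percentile bootstrap (2000 resamples) is
available as `method = "bootstrap"` and as a cross-check. A zero
confidence level degenerates to the point estimate; classes with fewer
than 5 members trigger an instability warning. The reported operating
point maximises Youden's $J =$ sensitivity $+$ specificity $- 1$, the
criterion consistent with reporting a Youden index; $J$-ties resolve to
the lower (more sensitive) threshold.

## The synthetic cohort generator

No patient-level data are deposited, so `simulate_cohort()` emulates the
documented cohort structure:

* baseline VAS from a normal(6.8, 1.8) truncated to $[3, 10]$ — the
  simplest generator matching the printed median 6.8 and range 3.0–10.0;
* remission onset $t^*$ uniform over sessions 2–8, giving the observed
  heterogeneity of courses: early-onset fast curves look like full "S"
  shapes inside the window, late-onset slow ones look near-linear (a
  default cohort contains both, which the tests assert via the straight-
  line $R^2$ of the noise-free curves);
* additive Gaussian measurement noise, sd 0.3 VAS — unstated clinically,
  chosen small relative to the 1.2-point MCSD — followed by clipping to
  $[0, 10]$ and rounding to 0.1, the resolution of a ruler on a 10 cm
  line (the printed summaries carry one decimal);
* 14 covariates with documented distributions (age normal 53.1/15.2
  truncated to 17–87, gender Bernoulli 89/142, protrusion diameter,
  degeneration grades, symptom-to-operation time, eight standard-normal
  fillers) and a binary outcome from a logistic link on the standardised
  covariates. Default effects give the five named clinical predictors
  decreasing weight — protrusion sagittal diameter largest — so that
  importance-recovery tests have a known answer; the intercept implies a
  65% good-efficacy prevalence, a majority-improves cohort consistent
  with the median pain drop from 6.8 to 4.3. The link and its
  coefficients are recorded in the output metadata.

**The anchored-rate design.** In the default mode the generator is
*self-consistent with the asymptote rule*: $K$ is set by
`compute_upper_asymptote()` on the drawn baseline and the rate is derived
as $b = \mathrm{logit}(\min(\mathrm{VAS}_1/K,\, 0.97)) / (t^* - 1)$, so
the noise-free curve passes through the baseline at session 1 and the $K$
the fitting procedure reconstructs from that first score is *exactly* the
generating $K$. This is what makes exact parameter recovery a meaningful
test: fitted $(a, b)$ return to the generating values at optimiser
precision and the pooled $R^2$ of a noise-free cohort is 1. The price is
that the rate is a deterministic function of baseline and onset rather
than an independent lognormal draw; `baseline_anchored = FALSE` restores
the free lognormal rate (meanlog $\log 0.7$, sdlog 0.5) with $K$ anchored
through the baseline instead — more dispersed, but then the fitted and
generating asymptotes differ by construction and recovery is only
approximate. The 0.97 ratio cap keeps rates finite for baselines at the
top of the scale.

What the generator does **not** emulate: dropout or missing sessions
(the modelled cohort completes all ten), non-monotone flare-ups beyond
symmetric noise, floor effects in reporting (a patient rating 0 repeatedly),
correlation between trajectory shape and covariates (outcome links to
covariates only), and any real-data covariate correlation structure.
Passing tests therefore demonstrate that the *procedures* are correct and
well-behaved under realistic magnitudes — not that the real cohort's
printed values are reproduced, which without the data is out of reach.

## Problem sizes and numerical choices

The test suite and the acceptance script run on deliberately modest
sizes, chosen to exercise every code path at comfortable margins:
cohorts of 142 (the reference size) for trend checks, 200 noise-free
patients for parameter recovery, 2000 for distributional Monte-Carlo
checks, boosting runs of 25–150 trees for algebraic identities (the
default 1000-tree configuration is used in the end-to-end pipeline,
which completes in a few seconds), and 100 random small instances for
the AUC/concordance identity. Grid-search oracles for the curve fit use
an $(a, b)$ lattice of step 0.05 × 0.02 over $[-20, 20] \times [0, 5]$.

## Known limitations

* The logistic parameterisation with fixed asymptotes is one defensible
  reading of a curve "with upper and lower asymptotes"; Gompertz or
  free-slope four-parameter logistic alternatives are deliberately out of
  scope.
* Least-squares boosting of a 0/1 label yields scores that are not
  calibrated probabilities; clipping to $[0, 1]$ is a pragmatic device,
  and the logistic mode exists precisely because of this.
* With two observations and two free parameters the truncated $m = 2$
  "model" is an interpolation; its poor extrapolation is informative
  about the design, not a defect of the optimiser.
* DeLong intervals are asymptotic; at test-set sizes around 40 they are
  serviceable but the bootstrap cross-check is worth running when the
  AUC is near 1, where both methods compress against the boundary.
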