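# remcurve

Logistic remission-curve modelling and early efficacy prediction for
physiotherapy pain trajectories in lumbar disc herniation.

## The problem

Patients with lumbar disc herniation treated by physical therapy (traction,
joint loosening, physical-factor therapy) rate their pain on the 0–10
visual analogue scale (VAS) before each of ten sessions. Two clinical
questions drive the analysis:

1. **Can the remission course be expressed mathematically?** Pain relief
   is modelled as a decreasing logistic curve between two asymptotes,

   y(x) = lower + H / (1 + exp(a + b·x)),  H = K − lower,

   where x is the session index, K is the upper asymptote, `lower`
   (default 0) the lower one, a locates the onset of relief (the
   inflection sits at x = −a/b) and b is the descent rate. Following the
   minimal clinically significant difference (MCSD) for the VAS, K is
   anchored 1.2 points above the first rating: K = VAS₁ + 1.2, capped at
   10 (i.e. K = 10 whenever VAS₁ ≥ 8.8). Only (a, b) are estimated, by
   bounded least squares. Fit quality is summarised per patient by R² and
   across the cohort by the pooled ("global") R² = 1 − ΣSSres/ΣSStot.

2. **How early can the outcome be predicted?** For each treatment length
   m = 2..9 the curve is refitted on sessions 1..m and extrapolated to
   session 10. A course is *clinically effective* when the VAS falls by
   more than 1.2 points; the truncated model *predicts effectiveness
   successfully* when its predicted classification agrees with the
   observed one, and *predicts the remission magnitude successfully* when
   the predicted final VAS is within 1.2 points of the measured one.
   Success rates per m are compared by Pearson chi-square, with cells
   pooled into length groups (2–4 vs 5–9; 2–4 / 5–7 / 8–9) to limit
   multiple comparisons.

Alongside the curve model, a **gradient-boosting machine** built from
scratch classifies good vs poor efficacy from 14 baseline covariates
(protrusion sagittal diameter, segment degeneration grades, age, time
from symptom onset to operation, gender, ...). It is literal
forward-stagewise least-squares boosting: F₀(x) = 0, residuals rᵢ = yᵢ;
at each of M iterations a depth-limited CART regression tree is fitted to
the residuals and added with shrinkage μ, Fₘ = Fₘ₋₁ + μ·f̂ₘ,
rᵢ ← rᵢ − μ·f̂ₘ(xᵢ), so F_M(x) = Σₘ μ·f̂ₘ(x). Defaults follow the tuned
tuple (M = 1000, μ = 0.1, depth 4, min split 2, min leaf 1, subsample 1,
sqrt feature subsampling, seed 10) with a 7:3 train/test split. Models
are assessed by ROC analysis: trapezoidal AUC (= Mann–Whitney
concordance), DeLong or bootstrap 95% CI, and the Youden-optimal
operating point (J = sensitivity + specificity − 1).

Because the clinical dataset is not publicly deposited, the package ships
a **synthetic cohort generator** that reproduces the documented structure
(baseline VAS ~ normal(6.8, 1.8) truncated to [3, 10]; remission onset
uniform over sessions 2–8; both S-shaped and near-linear courses;
measurement noise sd 0.3; ruler rounding to 0.1; covariates linked to the
outcome through a logistic model), so the whole analysis is reproducible
end to end.

## Worked example

```r
library(remcurve)

traj <- vas_trajectory("P001", 1:10,
                       c(6.8, 6.4, 5.1, 3.4, 2.1, 1.3, 0.9, 0.7, 0.6, 0.5))
fit <- fit_patient(traj)
fit
#> Remission-curve fit, patient P001 (n = 10)
#>   K = 8.000, a = -2.5394, b = 0.6840, SSE = 0.6434, R2 = 0.9884

# predict the end-of-course pain from the first four sessions only
f4 <- fit_truncated(traj, 4)
predict_final_vas(f4)
#> [1] 0.07
classify_effectiveness(6.8 - 0.5)   # observed decline 6.3 > 1.2
#> [1] TRUE
```

K = 8.0 is the first rating 6.8 plus one MCSD; the fitted onset −a/b ≈
3.7 places the inflection near session 4, and the four-session fit
already extrapolates a final VAS of 0.07, within 1.2 of the measured 0.5
(a remission-magnitude success).

The full pipeline on the default 142-patient synthetic cohort:

```r
res <- run_pipeline(pipeline_config(out_dir = "run1"))
```

writes `fits.csv`, `predictions.csv`, the two success tables,
`comparisons.json`, `importance.csv`, `roc.json` and a `report.txt`
containing, for example:

```
Global coefficient of determination (pooled): 0.9841

Effectiveness-prediction success by treatment length:
  1st-2nd  114 successful (80.3%),  28 unsuccessful
  ...
  1st-9th  142 successful (100.0%),   0 unsuccessful

Pooled comparison [effectiveness_2to4_vs_5to9]: chi2 = 64.097, df = 1, p = 1.184e-15

Gradient-boosting evaluation (held-out test set):
  AUC = 0.793  [95% CI 0.649 - 0.937]
  Youden-optimal point: sensitivity 0.720, specificity 0.824, J = 0.544

Top five features by split-gain importance:
  1. sagittal_diameter_protrusion   0.2934
```

Success percentages rise steeply with the number of sessions used —
predictions from five or more sessions are far more reliable than from
two to four, and the synthetic generator's dominant covariate tops the
importance ranking.

## Package layout

- `R/synthetic-cohort.R` — cohort and covariate simulation
- `R/trajectory-model.R` — asymptote rule, logistic curve, per-patient fits, R²
- `R/truncated-prediction.R` — truncated fits, MCSD scoring, success tables, pooled chi-square
- `R/gbm.R` — regression trees, least-squares boosting, importance, 7:3 split
- `R/evaluation.R` — ROC, AUC, confidence intervals, Youden operating point
- `R/pipeline.R` — file formats and the end-to-end run
- `vignettes/remission-curves.Rmd` — methods and design notes
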