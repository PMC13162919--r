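---
title: "Methods: multimodal late-fusion survival modeling in fusesurv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal late-fusion survival modeling in fusesurv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`fusesurv` combines three patient-data modalities — a high-dimensional
radiomic feature table, clinical staging, and demographics — into
individualized survival risk for NSCLC-like cohorts. This vignette is the
package's own account of the models it fits, the numerical choices it
makes, what its synthetic data generator does and does not emulate, and
what a green test establishes.

## 1. Survival model core

Time-to-event outcomes are modeled with the Cox proportional-hazards
model, `h(t|x) = h0(t) exp(x'β)`, with an unspecified baseline hazard.
Estimation maximizes the log partial likelihood with Breslow's handling of
tied event times; ties are frequent in real registry data and Breslow
keeps the penalized solver's gradient simple (the gradient of the negative
log partial likelihood is `X'(μ − δ)`, where `μ_j = exp(η_j) H0(t_j)` is
the expected event count for patient *j* under the current fit). Fitting
is Newton–Raphson with step-halving; convergence requires a gradient
max-norm below `1e-8` within 50 iterations, and diverging coefficients
(`|β_j|·sd_j > 30`) raise an explicit monotone-likelihood/separation
error rather than returning garbage.

The baseline cumulative hazard is the Breslow step function over the
*training* event times; held-out patients are always scored with the
training-fold baseline. Absolute risk at the landmark `t* = 1.5` years —
approximately the median follow-up of the emulated cohort — is
`1 − exp(−H0(t*) exp(x'β))`, i.e. one minus the predicted survival
probability. If `t*` exceeds the last observed training time the last
baseline value is carried forward with a warning (no hazard is
extrapolated).

## 2. Group-lasso radiomic signature

Radiomic features come in predefined families (first-order, shape, GLCM,
GLRLM, GLSZM, GLDM, NGTDM) whose members are strongly correlated by
construction. The radiomic stage therefore penalizes the Cox partial
likelihood with the group-lasso penalty

```
f(β) = nll(β)/n + λ Σ_g w_g ‖β_g‖₂,    w_g = √p_g
```

— an ℓ₂ norm within each family and an ℓ₁ norm across families, so entire
families enter or leave together. `√p_g` weights are the standard choice
countering selection bias toward large families; the weight rule is a
config option since other data-adaptive rules exist.

**Solver.** The path is computed over a decreasing log-spaced λ grid
(default 100 points from `λ_max = max_g ‖∇_g ℓ(0)‖/w_g` down to
`0.001 λ_max`), warm-started, with an active-set strategy: solve on the
currently active families, certify group-level KKT conditions on all
families, and grow the active set with violators. Each active-set
subproblem is solved by proximal Newton: the partial likelihood is locally
majorized by its weighted Gram quadratic `X' diag(μ) X` (which dominates
the true Hessian, whose risk-set terms subtract rank-one corrections), the
penalized quadratic is minimized exactly by block-coordinate descent with
blockwise soft-thresholding in each family block's eigenbasis (a
one-dimensional secular equation per block update, solved by safeguarded
Newton), and a backtracking line search on the true objective guarantees
monotone decrease. Every reported path point satisfies the KKT conditions
within `1e-6` (the acceptance suite certifies this).

**Degenerate deep end.** When a λ grid reaches the effectively
unpenalized regime with more features than events (routine inside
cross-validation splits of small cohorts), no minimizer exists (monotone
likelihood). The single-fit API raises the error the caller should see;
inside cross-validation the path is truncated at the last solvable λ
(the glmnet/grpreg convention) and selection is restricted to λ values
fit in every fold.

**Selection.** The penalty level is chosen by Verweij–van Houwelingen
cross-validated deviance: for each fold, `−2[ℓ_full(β_−f) − ℓ_−f(β_−f)]`,
minimized over λ (a one-standard-error option exists but the default is
the minimum, consistent with a final signature of a handful of features).
The final radiomic model *refits an unpenalized Cox* on the selected
features: the signature is low-dimensional (events-per-variable well above
10), and refitting removes shrinkage bias from the risk scores that feed
the fusion stage. Both the penalized coefficients at the selected λ and
the refit are retained; the selection-frequency table reports, per
feature, the number of outer folds with a nonzero penalized coefficient
and the zero-inclusive mean coefficient.

## 3. Nested cross-validation and late fusion

Outer folds (default 5) are stratified by event status with near-equal
sizes. Inside each outer training fold: predictors are standardized with
training-fold statistics only; the clinical Cox (overall stage, T stage,
N stage as centered ordinal codes), demographic Cox (age, gender) and the
radiomic signature are fit on training data only; held-out patients
receive linear predictors, absolute risks at `t*` and survival curves from
the training baselines. The resulting out-of-fold (OOF) modality scores
are the only inputs the fusion stage ever sees, so no patient's
meta-feature comes from a model trained on that patient.

Five meta-learners consume the three OOF scores, trained per outer fold
on the training patients and scored on the held-out fold:

- **Cox fusion** — a Cox model on the three scores (the package's own
  engine). Rank-deficient score matrices (e.g. a constant radiomic score
  when the signature is empty) drop constant columns and fall back to a
  tiny ridge with a warning.
- **Weighted averaging** — scores are rank-transformed to [0, 1] with
  training-fold statistics (raw linear predictors live on
  modality-specific scales), then combined with equal weights or with
  simplex-grid weights (resolution 0.05) maximizing the training-fold
  C-index; ties break toward equal weights for determinism.
- **Logistic stacking** — the outcome is dichotomized at the landmark
  (event by `t*` = 1, under observation past `t*` = 0); patients censored
  before `t*` carry no label and are excluded from meta-training but are
  still scored. An elastic-net logistic model (glmnet) is tuned over the
  mixing grid α ∈ {0, 0.25, 0.5, 0.75, 1} and penalty strength by inner
  5-fold cross-validated binomial deviance. An IPCW-weighted variant of
  the exclusion rule would be a straightforward extension; exclusion is
  the simplest defensible default.
- **Random survival forest** — called through the shipped Python helper
  (scikit-survival); tuned per outer fold by seeded random search of 60
  of the 224 grid configurations (mtry 1–2, node size 5–30, 500–1500
  trees, 1–10 splits), selected by inner-CV C-index. The "number of
  splits" dimension has no counterpart in the available learner and maps
  to the minimum-samples-to-split parameter, preserving grid cardinality.
- **Gradient-boosted trees** — the binary event-by-`t*` objective with
  the same exclusion rule as logistic stacking (mirroring the stacking
  horizon; a Cox-loss objective would be an alternative), exhaustive
  3 × 3 depth × learning-rate grid, selected by inner-CV log-loss,
  100 boosting rounds.

Fused survival curves come from the model's native baseline where one
exists (Cox fusion, the unimodal models, the survival forest); score-only
learners (weighted average, logistic stack, boosted trees) are calibrated
through a one-parameter Cox fit of the training outcomes on the fused
score, which supplies a Breslow baseline for absolute risk at any horizon.
A constant fused score degrades gracefully to the null (baseline-only)
model.

Whole-dataset ("full data") performance columns refit every model on all
patients and evaluate in-sample; they are reported alongside the
cross-validated columns because the contrast between the two is itself
informative (tree ensembles look far better in-sample), but all
conclusions should rest on the cross-validated numbers.

## 4. Outcome-guided risk groups

Per outer training fold, candidate cutoff pairs are drawn from the
quantile grid of the absolute-risk scores restricted to the central
15th–85th percentile band in steps of 0.025 (plus the tercile pair, which
serves as the argmax-dominance anchor and tie-break target). A pair is
feasible if each of the three groups holds at least 15 % of patients and
the per-group event rates are non-decreasing from low to high; among
feasible pairs the log-rank χ² (K-sample, hypergeometric variance) is
maximized. The five fold cutoff pairs are averaged arithmetically on the
absolute-risk scale and applied to every patient's OOF risk. Group
summaries report n, events, event rate and the Kaplan–Meier median
(reported as not-reached when the curve never crosses 0.5).

Because the cutoffs are chosen to maximize a test statistic, the selected
χ² is *selection-inflated*: under a null (scores independent of outcome)
it exceeds the nominal 5.99 threshold far more often than 5 %. The
package documents and tests this behavior; the χ² should be read as a
separation score, not as a calibrated p-value.

The band (15–85 %), minimum group fraction (0.15) and the monotone
quantity (event rate) are conventions: the constraints' existence is part
of the method, their values are not published, and all three are exposed
as configuration.

## 5. Evaluation suite

All metrics are implemented from scratch and verified against brute-force
oracles:

- **Harrell C-index** — comparable pairs are those whose earlier time is
  an event; score ties credit 0.5. Invariant under monotone transforms.
- **Time-dependent AUC** — cumulative/dynamic: cases have events by `t`,
  controls are under observation beyond `t`; cases are weighted by
  `1/G(T_i−)` where `G` is the Kaplan–Meier estimate of the censoring
  distribution. The incident/dynamic variant is out of scope.
- **Brier score** — Graf's IPCW form: events before `t` weighted by
  `1/G(T_i−)`, survivors by `1/G(t)`, patients censored before `t`
  contribute through the `1/n` normalization only. The integrated Brier
  score is the trapezoidal average over `[0, τ]` with `BS(0) = 0`
  prepended.
- **Evaluation grid** — deciles of observed event times clipped to
  `[0.25, τ]` with `τ = 0.8 ×` the largest observed time; the "AUC"
  column is the mean over that grid. Both choices are conventions
  (exposed as arguments) since no canonical grid exists.
- **Calibration** — per group (risk strata or quantile bins), mean
  predicted risk against `1 − KM(t)`; slope and intercept from ordinary
  least squares of observed on predicted across group points (ideal: 1
  and 0).
- **Intervals** — optional seeded patient-level percentile bootstrap
  (200 resamples by default). Whether published bracketed intervals are
  bootstrap or across-fold ranges is not knowable from the text; the
  bootstrap is the package's choice and is labeled as such.

## 6. The synthetic cohort generator

`cohort_spec()` defaults encode the emulated cohort: n = 398, stage mix
(21.1, 9.3, 69.6) %, age N(68.1, 10.1²), 68.6 % male, 11.8 % expected
censoring, and 107 radiomic features in the standard 7-family taxonomy
(18/14/24/16/16/14/5 — only the total of 107 is externally fixed; the
split is the standard taxonomy's). Radiomic features are zero-mean
Gaussian with equicorrelation 0.5 within each family (one shared factor
per family) and independence across families, then shifted and scaled per
family so families live on visibly different scales, as real radiomic
families do. Event times follow a Weibull proportional-hazards model
(shape 1.2; scale calibrated once — a fixed 1.38 inflation of the
linear-predictor-zero value — so the default cohort's median observed
survival is ≈ 1.5 years). The log-hazard sums the radiomic contribution
(defaults: effects −0.30, 0.30, 0.20, 0.08, −0.05 on the standardized
NGTDM features, echoing a five-feature texture signature with mixed
signs), centered stage/T/N ordinal effects (0.30, 0.08, 0.08) and
demographic effects (0.12 per SD of age, 0.15 for male). These effect
sizes were chosen once to land cross-validated discrimination in the
high-0.5s — the modest regime reported for cohorts of this kind — and are
not revisited. Censoring is exponential and independent of covariates
(the simplest mechanism satisfying the independent-censoring assumption);
its rate is calibrated by root-finding on a 20 000-draw pilot sample so
the expected censored fraction matches the target. T/N stages are drawn
from simple conditional tables given overall stage — a declared synthetic
convention, as is every radiomic feature scale: the generator reproduces
the *statistical skeleton* the analysis assumes, not real radiomic
marginal distributions, inter-family correlation, non-proportional
hazards, or missing-data mechanisms. A green test on synthetic data
therefore establishes the correctness and leakage-freedom of the
machinery, not clinical performance.

## 7. Computational scaling in the test suite

The acceptance criteria pin what matters statistically (n = 2000 and 20
seeds for selection consistency, n = 5000 for calibration recovery, all
thresholds); quantities that are purely computational knobs are scaled in
the tests and documented here: the λ grid uses 12–25 points instead of
100 (resolution only affects how finely the same path is sampled), the
permutation canary runs on a 21-feature reduced taxonomy at n = 150
(a chance-level null does not depend on feature count, and a leak would
surface regardless), tree grids are subsampled with small forests and
inner k = 3 (the null and determinism properties under test are
grid-independent), and the canary path stops at `0.05 λ_max` (the p ≈ n
overfit regime below that is irrelevant under a permuted outcome). The
package defaults remain the full-scale settings.

## 8. Known limitations

- The fused models inherit the proportional-hazards assumption wherever a
  Cox calibration supplies the survival curve; only the survival forest
  produces genuinely non-PH curves.
- The log-rank-maximizing cutoff search yields optimistically large χ²
  (Section 4); downstream hazard ratios for risk groups share that
  selection optimism.
- The logistic and boosted-tree stacks discard patients censored before
  the landmark from meta-training; with heavy early censoring an IPCW
  variant would be preferable.
- The C-index implementation is O(n²) in comparable pairs; adequate for
  cohort sizes in the hundreds to low thousands, not for biobank scale.
- Group-lasso path truncation in CV means very small λ values may be
  unavailable for selection in small cohorts — by construction those
  values index models with no maximizer.
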