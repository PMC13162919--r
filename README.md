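# fusesurv

Multimodal late-fusion survival modeling for non-small cell lung cancer
(NSCLC) prognosis from tabular radiomic, clinical and demographic data.

Anatomical staging alone discriminates poorly between NSCLC patients with
very different outcomes. `fusesurv` implements a complete, leakage-audited
pipeline for combining three patient-data modalities into individualized
absolute-risk estimates and three-level prognostic groups:

1. **Radiomic signature** — a group-lasso penalized Cox model over 107
   radiomic features organized into 7 families (first-order, shape, GLCM,
   GLRLM, GLSZM, GLDM, NGTDM). The penalty
   `λ Σ_g w_g ‖β_g‖₂` (with `w_g = √p_g`) applies an ℓ₂ norm within each
   family and an ℓ₁ norm across families, so whole families are retained
   or dropped together. The penalty level is chosen by cross-validated
   partial-likelihood deviance (Verweij–van Houwelingen), and the final
   low-dimensional signature is refit unpenalized.
2. **Late fusion** — within a nested 5-fold cross-validation, out-of-fold
   modality risk scores (clinical Cox on overall/T/N stage, demographic
   Cox on age and gender, radiomic Cox on the signature) feed five
   meta-learners: Cox fusion, weighted averaging (equal or C-index-
   optimized simplex weights), elastic-net logistic stacking at the
   1.5-year landmark, a random survival forest, and gradient-boosted
   trees. No patient is ever scored by a model that saw them in training.
3. **Risk stratification** — absolute risk at the 1.5-year landmark
   (`1 − S(t*|x)` under the training-fold Breslow baseline) is split into
   low/medium/high groups by an outcome-guided two-cutoff search that
   maximizes the log-rank χ² subject to minimum group-size and monotone
   event-rate constraints; fold-specific cutoffs are averaged and applied
   to held-out patients.
4. **Evaluation** — Harrell's C-index, cumulative/dynamic time-dependent
   AUC and Brier/integrated-Brier scores with inverse-probability-of-
   censoring weights, Kaplan–Meier summaries, and group-level calibration
   slope/intercept, all implemented from scratch and tested against
   brute-force oracles.

A seeded synthetic cohort generator emulates the structure of the public
Lung1 cohort (n = 398, 88.2 % events, stage mix 21.1/9.3/69.6 %, age
N(68.1, 10.1²), 68.6 % male, median survival 1.5 years, block-correlated
radiomic families, Weibull proportional-hazards outcome, calibrated
independent censoring), so the entire pipeline is testable without any
data download. The generator is first-class, tested code — see
`?cohort_spec`.

## Worked example

```r
library(fusesurv)

spec   <- cohort_spec(seed = 42)          # default Lung1-like cohort, n = 398
cohort <- generate_cohort(spec)
cohort
#> Synthetic cohort: 398 patients, 107 radiomic features in 7 families
#>   events: 353 (88.7%), median follow-up 1.47 y

y     <- cohort_outcome(cohort)
folds <- make_outer_folds(y, k = 5, seed = 1)
mf    <- oof_modality_scores(cohort, folds, seed = 2, nlambda = 15,
                             lambda_min_ratio = 0.05, grlasso_tol = 1e-4)

# which radiomic features survive the group lasso, per outer fold?
selection_frequency(lapply(mf$fold_details,
                           function(d) d$radiomic$penalized_coef))[1:5, ]
#>  feature  coefficient selection_frequency
#> ngtdm_03  0.154727123                   5
#> ngtdm_01 -0.107039921                   5
#> ngtdm_02  0.066329389                   5
#> ngtdm_04  0.041302674                   5
#> ngtdm_05 -0.003451811                   5

fusion <- fit_cox_meta(mf, y)             # Cox late-fusion meta-learner
evaluate_model(fusion$oof_score, fusion$oof_surv, y)
#> C-index 0.5997 | mean td-AUC 0.6495 | IBS 0.1758 (tau = 12.82)

fold_averaged_stratification(fusion$oof_risk, folds, y)
#> Risk stratification: cutoffs (0.3413, 0.5061), log-rank chi-sq 39.06
#>   group   n events event_rate km_median
#>     low  84     70  0.8333333  2.986851
#>  medium 134    118  0.8805970  1.951593
#>    high 180    165  0.9166667  1.306909
```

The generator planted its radiomic signal in the NGTDM family; the
group-lasso stage recovers exactly those five features in all five outer
folds. The cross-validated Cox-fusion C-index of 0.60 says that for 60 %
of comparable patient pairs the fused score ranks the shorter survivor as
higher-risk. The stratification splits the cohort at mean absolute-risk
cutoffs 0.34 and 0.51, giving groups whose observed event rates (0.83 →
0.92) and Kaplan–Meier median survival times (3.0 → 1.3 years) are
monotone in the assigned risk, with a 2-df log-rank χ² of 39.1.

`run_pipeline(run_config(spec = cohort_spec(), seed = 1, out_dir = "out"))`
runs all eight models (three unimodal + five fusion) end to end and writes
the full CSV report bundle: performance (whole-data and cross-validated
C-index/AUC/IBS per model), signature selection frequencies,
events-per-variable, risk-group distributions, cutoffs and log-rank
statistics, calibration slopes/intercepts, a stage-by-risk-group
contingency table, tidy Kaplan–Meier curves, and hazard ratios for risk
groups and stage. A command-line front end is shipped in
`inst/cli/fusesurv` (`simulate`, `fit-signature`, `fuse`, `stratify`,
`evaluate`, `run-all`).

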